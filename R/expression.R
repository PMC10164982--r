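#' Group comparison with normality-dependent test choice
#'
#' Values are expected on a log scale (Ct-derived quantities already are).
#' Each group is tested for normality with the Shapiro-Wilk test; if both
#' groups pass at `alpha_norm` the two-sided Student's t-test (equal
#' variances) is used, otherwise the two-sided Mann-Whitney U test. A
#' constant group counts as non-normal.
#'
#' @param x,y numeric values for the two groups (>= 3 each).
#' @param alpha_norm normality-test level (default 0.05).
#' @return list: `p_value`, `test_used` (`"t-test"` or `"mann-whitney"`),
#'   `shapiro_p` (length-2).
#' @export
group_test <- function(x, y, alpha_norm = 0.05) {
  if (length(x) < 3 || length(y) < 3) {
    stop("each group needs at least 3 values (got ", length(x), " and ",
         length(y), ")")
  }
  swp <- vapply(list(x, y), function(v) {
    if (sd(v) == 0) return(0)            # degenerate: treat as non-normal
    shapiro.test(v)$p.value
  }, numeric(1))
  if (all(swp > alpha_norm)) {
    list(p_value = t.test(x, y, var.equal = TRUE)$p.value,
         test_used = "t-test", shapiro_p = swp)
  } else {
    list(p_value = wilcox.test(x, y, exact = FALSE)$p.value,
         test_used = "mann-whitney", shapiro_p = swp)
  }
}

# ratio >= 1 stays a ratio; ratio < 1 becomes the negative reciprocal,
# so |fc_reported| >= 1 always and down-regulation reads as a negative fold.
fc_signed <- function(fc_linear) {
  ifelse(fc_linear >= 1, fc_linear, -1 / fc_linear)
}

#' Relative quantification by the 2^-ddCt method
#'
#' For each gene, `ddCt_s = dCt_s - mean(dCt over control samples)`; the
#' per-sample relative expression is `2^-ddCt` and the group-level fold
#' change is `2^-(mean ddCt of tumor samples)` (a geometric-mean-type
#' summary). Reported fold changes follow the signed convention: ratios
#' below 1 appear as the negative reciprocal (0.25 becomes -4). Group
#' differences are tested on the dCt values with [group_test()];
#' Benjamini-Hochberg adjusted p-values are reported alongside the raw ones.
#'
#' @param normalized a `normalized_matrix` from [delta_ct()] or a bare
#'   gene x sample dCt matrix.
#' @param groups `"tumor"`/`"control"` per sample (matched to columns).
#' @param alpha_norm normality-test level passed to [group_test()].
#' @return data.frame of class `fold_change_result`, one row per gene:
#'   `gene`, `mean_ddct`, `fc_linear`, `fc_reported`, `p_value`, `padj`,
#'   `test_used`. The per-sample ddCt matrix is attached as attribute
#'   `"ddct"`.
#' @export
ddct_fold_change <- function(normalized, groups, alpha_norm = 0.05) {
  dct <- if (inherits(normalized, "normalized_matrix")) {
    normalized$delta_ct
  } else {
    normalized
  }
  stopifnot_matrix(dct, what = "delta_ct")
  groups <- as.character(groups)
  if (length(groups) != ncol(dct)) {
    stop("'groups' must have one entry per sample")
  }
  t_cols <- which(groups == "tumor")
  c_cols <- which(groups == "control")
  if (length(c_cols) == 0) stop("control group is empty")
  if (length(t_cols) == 0) stop("tumor group is empty")
  if (anyNA(dct)) stop("delta-Ct matrix contains undetected cells")

  ctrl_mean <- rowMeans(dct[, c_cols, drop = FALSE])
  ddct <- sweep(dct, 1, ctrl_mean, "-")
  rows <- lapply(rownames(dct), function(g) {
    m <- mean(ddct[g, t_cols])
    fc <- 2^(-m)
    gt <- group_test(dct[g, t_cols], dct[g, c_cols], alpha_norm)
    data.frame(gene = g, mean_ddct = m, fc_linear = fc,
               fc_reported = fc_signed(fc),
               p_value = gt$p_value, test_used = gt$test_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p_value, method = "BH")
  out <- out[, c("gene", "mean_ddct", "fc_linear", "fc_reported",
                 "p_value", "padj", "test_used")]
  rownames(out) <- NULL
  attr(out, "ddct") <- ddct
  class(out) <- c("fold_change_result", "data.frame")
  out
}

#' Call significance on fold-change results
#'
#' A gene is significant iff its raw p-value is below `p_max` and its
#' reported (signed) fold change is at least `fc_min` in magnitude.
#'
#' @param result a [ddct_fold_change()] data.frame (or any frame with
#'   `p_value` and `fc_reported`).
#' @param p_max p-value threshold (default 0.05).
#' @param fc_min minimum |fold change| (default 2).
#' @return the input with `significant` (logical) and `direction`
#'   (`"up"`/`"down"`/`"ns"`) columns added.
#' @export
classify_significance <- function(result, p_max = 0.05, fc_min = 2) {
  sig <- result$p_value < p_max & abs(result$fc_reported) >= fc_min
  result$significant <- sig
  result$direction <- ifelse(!sig, "ns",
                             ifelse(result$fc_reported > 0, "up", "down"))
  result
}
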