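#' Reads-per-million normalization
#'
#' `rpm[m, s] = count[m, s] / sum(count[, s]) * 1e6`, so each sample column
#' sums to one million.
#'
#' @param counts miRNA x sample matrix of non-negative counts.
#' @return RPM matrix of the same shape.
#' @export
rpm_normalize <- function(counts) {
  stopifnot_matrix(counts, what = "counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero) > 0) {
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Discard features with no expression in any sample
#'
#' A miRNA (isoform) showing zero counts in every sample carries no signal
#' and is removed before any downstream screen.
#'
#' @param counts miRNA x sample count matrix.
#' @return list: `retained` (ids), `discarded` (ids), `counts` (retained
#'   submatrix), `n_input`, `n_retained`, `n_discarded`.
#' @export
expression_filter <- function(counts) {
  stopifnot_matrix(counts, what = "counts")
  expressed <- rowSums(counts) > 0
  list(retained = rownames(counts)[expressed],
       discarded = rownames(counts)[!expressed],
       counts = counts[expressed, , drop = FALSE],
       n_input = nrow(counts),
       n_retained = sum(expressed),
       n_discarded = sum(!expressed))
}

# base mean and tumor-vs-control log2FC of an RPM matrix (pseudocount on
# both group means to keep the ratio finite)
rpm_group_stats <- function(rpm, groups, pseudocount = 0.5) {
  groups <- as.character(groups)
  if (length(groups) != ncol(rpm)) {
    stop("'groups' must have one entry per sample")
  }
  t_cols <- groups == "tumor"
  c_cols <- groups == "control"
  if (!any(t_cols) || !any(c_cols)) {
    stop("both 'tumor' and 'control' groups must be non-empty")
  }
  data.frame(
    id = rownames(rpm),
    base_mean = rowMeans(rpm),
    mean_tumor = rowMeans(rpm[, t_cols, drop = FALSE]),
    mean_control = rowMeans(rpm[, c_cols, drop = FALSE]),
    log2fc = log2((rowMeans(rpm[, t_cols, drop = FALSE]) + pseudocount) /
                    (rowMeans(rpm[, c_cols, drop = FALSE]) + pseudocount)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Screen sequencing counts for endogenous-control candidates
#'
#' From RPM-normalized counts, miRNAs with mean abundance below `base_min`
#' or with `|log2FC| > lfc_max` between tumor and control groups are
#' discarded; the survivors are ranked by |log2FC| ascending (the most
#' group-invariant first) and the top `top_n` are returned as candidate
#' normalizers. The fold-change gate is two-sided: a strong change in either
#' direction disqualifies a normalizer.
#'
#' @param rpm miRNA x sample RPM matrix (see [rpm_normalize()]).
#' @param groups `"tumor"`/`"control"` per sample.
#' @param base_min minimum mean RPM (default 100).
#' @param lfc_max maximum |log2FC| (default 2).
#' @param top_n number of candidates to return (default 5).
#' @param pseudocount added to both group means before the ratio.
#' @return list: `candidates` (ids, best first), `table` (all miRNAs with
#'   `base_mean`, `log2fc`, `discarded`, `reason`).
#' @export
ec_candidate_screen <- function(rpm, groups, base_min = 100, lfc_max = 2,
                                top_n = 5, pseudocount = 0.5) {
  stats <- rpm_group_stats(rpm, groups, pseudocount)
  stats$reason <- ifelse(
    stats$base_mean < base_min, sprintf("base mean < %g", base_min),
    ifelse(abs(stats$log2fc) > lfc_max,
           sprintf("|log2FC| > %g", lfc_max), "")
  )
  stats$discarded <- stats$reason != ""
  surv <- stats[!stats$discarded, , drop = FALSE]
  surv <- surv[order(abs(surv$log2fc), surv$id), , drop = FALSE]
  if (nrow(surv) < top_n) {
    warning("only ", nrow(surv), " candidates survive the screen (top_n = ",
            top_n, ")")
  }
  list(candidates = utils::head(surv$id, top_n),
       table = stats[order(abs(stats$log2fc), stats$id), , drop = FALSE])
}

#' Consensus of differential-expression calls across methods
#'
#' Intersects the significant sets of several DE result tables (as produced
#' by count-based methods such as edgeR, voom or DESeq2, consumed here as
#' generic tables), then removes low-abundance members (`baseMean <
#' base_min` in the first table). Per-table counts and the Venn-style
#' intersection size are reported.
#'
#' @param tables list of data.frames with columns `id`, `baseMean`,
#'   `log2FC`, `pvalue`, `padj` (and optionally `significant`).
#' @param base_min minimum baseMean for consensus members (default 100).
#' @param alpha significance level applied to `padj` when no `significant`
#'   column is present.
#' @return list: `consensus` (ids passing intersection + abundance filter),
#'   `intersection` (ids before the abundance filter), `per_method`
#'   (significant counts per table), `dropped_low_expression`.
#' @export
de_consensus <- function(tables, base_min = 100, alpha = 0.05) {
  if (length(tables) < 2) stop("need at least 2 DE tables for a consensus")
  sig_sets <- lapply(tables, function(tab) {
    if (nrow(tab) == 0) stop("empty DE table")
    need <- c("id", "baseMean", "log2FC", "pvalue", "padj")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
      stop("DE table lacks column(s): ", paste(miss, collapse = ", "))
    }
    if ("significant" %in% names(tab)) {
      tab$id[tab$significant]
    } else {
      tab$id[tab$padj <= alpha]
    }
  })
  inter <- Reduce(intersect, sig_sets)
  inter <- sort(inter)
  first <- tables[[1]]
  bm <- first$baseMean[match(inter, first$id)]
  low <- inter[is.na(bm) | bm < base_min]
  list(consensus = setdiff(inter, low),
       intersection = inter,
       per_method = vapply(sig_sets, length, integer(1)),
       dropped_low_expression = low)
}
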