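#' geNorm expression stability (M value)
#'
#' For candidate reference genes j and k, the pairwise variation is the
#' standard deviation across samples of `Ct_j - Ct_k` (Ct is log2-scale, so
#' this is the SD of a log2 expression ratio). The M value of gene j is the
#' mean of its pairwise variations with every other gene; lower M means more
#' stable. The iterative pass repeatedly removes the gene with the highest M
#' and recomputes, until two genes remain; those two cannot be separated by
#' the method and share ranks 1-2. The pairwise-variation series `V(n/n+1)`
#' is the SD across samples of the difference between log-scale
#' normalization factors (mean Ct of the top n genes) built from the top n
#' and top n+1 genes.
#'
#' @param ct numeric gene x sample Ct matrix, at least 3 genes, 2 samples,
#'   no missing cells.
#' @return list: `m` (M value per gene, full panel), `rank` (rank from the
#'   iterative exclusion, final pair tied at 1.5), `exclusion_order` (genes
#'   from least to most stable as removed), `v` (data.frame `n`, `v` with
#'   `V(n/n+1)` for n = 2..G-1).
#' @export
genorm <- function(ct) {
  ct <- as_ct_values(ct)
  stopifnot_matrix(ct, min_genes = 3, min_samples = 2)
  if (anyNA(ct)) stop("genorm() requires a complete matrix (no missing cells)")
  genes <- rownames(ct)

  m_values <- function(x) {
    g <- nrow(x)
    m <- numeric(g)
    for (j in seq_len(g)) {
      sds <- vapply(seq_len(g)[-j],
                    function(k) sd(x[j, ] - x[k, ]), numeric(1))
      m[j] <- mean(sds)
    }
    setNames(m, rownames(x))
  }

  m_full <- m_values(ct)

  remaining <- ct
  excluded <- character(0)
  rank_out <- setNames(numeric(length(genes)), genes)
  while (nrow(remaining) > 2) {
    m <- m_values(remaining)
    worst <- names(which.max(m))
    rank_out[worst] <- nrow(remaining)
    excluded <- c(worst, excluded)
    remaining <- remaining[setdiff(rownames(remaining), worst), , drop = FALSE]
  }
  final_pair <- rownames(remaining)
  rank_out[final_pair] <- 1.5
  order_genes <- c(final_pair[order(m_full[final_pair])], excluded)

  n_max <- length(genes) - 1
  v <- if (n_max >= 2) {
    nf <- function(top) colMeans(ct[order_genes[seq_len(top)], , drop = FALSE])
    data.frame(
      n = 2:n_max,
      v = vapply(2:n_max, function(n) sd(nf(n) - nf(n + 1)), numeric(1))
    )
  } else {
    data.frame(n = integer(0), v = numeric(0))
  }

  list(m = m_full, rank = rank_out,
       exclusion_order = rev(order_genes),
       stability_order = order_genes, v = v)
}

#' NormFinder model-based stability
#'
#' Decomposes log-scale expression (Ct) into gene, sample and error terms
#' within each sample group, following the model-based analysis-of-variance
#' approach. Per gene g and group i the intra-group variance is estimated
#' from the two-way residuals with a bias correction for the number of genes
#' k: with `s2_gi` the residual mean square, `sigma2_gi = k/(k-2) *
#' (s2_gi - mean(s2_i)/(k-1))`, floored at zero. The inter-group difference
#' `d_gi` (the gene's centred group mean) is shrunk toward zero by the
#' empirical-Bayes factor `gamma2 / (gamma2 + sigma2_gi/n_i)`. The stability
#' value combines both sources with equal group weights:
#' `rho_g = mean_i(|d_gi(shrunk)| + sqrt(sigma2_gi/n_i))`; lower is more
#' stable. Without groups, `rho_g = sqrt(sigma2_g)` from the pooled fit.
#'
#' @param ct numeric gene x sample Ct matrix (>= 3 genes, no missing cells).
#' @param groups optional character/factor per sample with 2 levels, each
#'   with >= 2 samples; `NULL` for the group-free variant.
#' @return list: `rho` (stability per gene, cycles), `sigma2` (gene x group
#'   intra-group variances), `d` (gene x group shrunk inter-group
#'   differences; `NULL` when group-free).
#' @export
normfinder <- function(ct, groups = NULL) {
  ct <- as_ct_values(ct)
  stopifnot_matrix(ct, min_genes = 3, min_samples = 4)
  if (anyNA(ct)) {
    stop("normfinder() requires a complete matrix (no missing cells)")
  }
  k <- nrow(ct)

  gene_var <- function(x) {
    # two-way residuals and bias-corrected per-gene variance
    n <- ncol(x)
    r <- x - rowMeans(x) - rep(colMeans(x), each = nrow(x)) + mean(x)
    s2 <- rowSums(r^2) / (n - 1)
    pmax(k / (k - 2) * (s2 - mean(s2) / (k - 1)), 0)
  }

  if (is.null(groups)) {
    rho <- sqrt(gene_var(ct))
    return(list(rho = setNames(rho, rownames(ct)), sigma2 = rho^2, d = NULL))
  }

  groups <- as.character(groups)
  if (length(groups) != ncol(ct)) {
    stop("'groups' must have one entry per sample")
  }
  lev <- unique(groups)
  if (length(lev) != 2) stop("normfinder() expects exactly 2 groups")
  n_i <- table(factor(groups, levels = lev))
  if (any(n_i < 2)) {
    stop("each group needs at least 2 samples (got ",
         paste(n_i, collapse = ", "), ")")
  }

  sigma2 <- sapply(lev, function(l) gene_var(ct[, groups == l, drop = FALSE]))
  z <- sapply(lev, function(l) {
    gm <- rowMeans(ct[, groups == l, drop = FALSE])
    gm - mean(gm)
  })
  d <- z - rowMeans(z)                      # sums to 0 across groups
  v <- sweep(sigma2, 2, as.numeric(n_i), "/")  # sampling variance of d
  gamma2 <- max(0, sum(d^2) / (length(lev) * (k - 1)) - mean(v))
  shrink <- ifelse(gamma2 + v > 0, gamma2 / (gamma2 + v), 0)
  d_shrunk <- d * shrink
  rho <- rowMeans(abs(d_shrunk) + sqrt(v))

  list(rho = setNames(rho, rownames(ct)),
       sigma2 = sigma2, d = d_shrunk, gamma2 = gamma2)
}

#' BestKeeper descriptive stability statistics
#'
#' The BestKeeper index is the per-sample geometric mean of the candidate Ct
#' values. Each candidate is described by the standard deviation of its Ct
#' across samples (the ranking key: lower SD = more stable), the coefficient
#' of variation `CV = 100 * SD / mean(Ct)`, and the Pearson correlation of
#' its Ct with the index. A constant gene has undefined correlation (`NA`)
#' but still ranks best by SD.
#'
#' @param ct numeric gene x sample Ct matrix (>= 2 genes, >= 3 samples).
#' @return list: `stats` (data.frame `gene`, `sd`, `cv`, `r`), `index`
#'   (per-sample BestKeeper index).
#' @export
bestkeeper <- function(ct) {
  ct <- as_ct_values(ct)
  stopifnot_matrix(ct, min_genes = 2, min_samples = 3)
  if (anyNA(ct)) {
    stop("bestkeeper() requires a complete matrix (no missing cells)")
  }
  index <- apply(ct, 2, geom_mean)
  sds <- apply(ct, 1, sd)
  r <- vapply(seq_len(nrow(ct)), function(g) {
    if (sds[g] == 0 || sd(index) == 0) NA_real_ else cor(ct[g, ], index)
  }, numeric(1))
  list(
    stats = data.frame(gene = rownames(ct),
                       sd = unname(sds),
                       cv = unname(100 * sds / rowMeans(ct)),
                       r = r,
                       stringsAsFactors = FALSE),
    index = index
  )
}

#' Comparative delta-Ct stability
#'
#' For every ordered pair of candidates the Ct difference is computed per
#' sample; if that difference is constant across samples, both genes vary in
#' parallel and are considered stable. The stability of gene j is the mean
#' over all partners k of the SD across samples of `Ct_j - Ct_k`; lower
#' means more stable.
#'
#' @param ct numeric gene x sample Ct matrix (>= 2 genes, >= 2 samples).
#' @return named numeric vector of mean pairwise SDs (cycles).
#' @export
deltact_stability <- function(ct) {
  ct <- as_ct_values(ct)
  stopifnot_matrix(ct, min_genes = 2, min_samples = 2)
  if (anyNA(ct)) {
    stop("deltact_stability() requires a complete matrix (no missing cells)")
  }
  g <- nrow(ct)
  out <- vapply(seq_len(g), function(j) {
    mean(vapply(seq_len(g)[-j],
                function(k) sd(ct[j, ] - ct[k, ]), numeric(1)))
  }, numeric(1))
  setNames(out, rownames(ct))
}

#' Run all four stability methods on one Ct matrix
#'
#' Convenience wrapper producing the per-gene stability report consumed by
#' [aggregate_ranks()]: geNorm M value and exclusion-order rank, NormFinder
#' stability, BestKeeper SD/CV/r, and the comparative delta-Ct mean pairwise
#' SD.
#'
#' @param ct numeric gene x sample Ct matrix.
#' @param groups optional 2-level group vector for NormFinder (others are
#'   group-blind).
#' @return data.frame of class `stability_report`, one row per gene:
#'   `gene`, `genorm_m`, `genorm_rank`, `normfinder_rho`, `bestkeeper_sd`,
#'   `bestkeeper_cv`, `bestkeeper_r`, `deltact_stability`.
#' @export
stability_report <- function(ct, groups = NULL) {
  ct <- as_ct_values(ct)
  gn <- genorm(ct)
  nf <- normfinder(ct, groups)
  bk <- bestkeeper(ct)
  dc <- deltact_stability(ct)
  out <- data.frame(
    gene = rownames(ct),
    genorm_m = unname(gn$m[rownames(ct)]),
    genorm_rank = unname(gn$rank[rownames(ct)]),
    normfinder_rho = unname(nf$rho[rownames(ct)]),
    bestkeeper_sd = bk$stats$sd[match(rownames(ct), bk$stats$gene)],
    bestkeeper_cv = bk$stats$cv[match(rownames(ct), bk$stats$gene)],
    bestkeeper_r = bk$stats$r[match(rownames(ct), bk$stats$gene)],
    deltact_stability = unname(dc[rownames(ct)]),
    stringsAsFactors = FALSE
  )
  attr(out, "genorm_v") <- gn$v
  class(out) <- c("stability_report", "data.frame")
  out
}
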