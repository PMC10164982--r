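#' Collapse technical replicates to per-sample Ct values
#'
#' Each (gene, sample) cell becomes the arithmetic mean of its detected
#' replicates (undetected replicates, stored as `NA`, are ignored). A QC flag
#' is raised when the replicate SD exceeds `max_sd`. A cell whose replicates
#' are all undetected stays undetected. The median is available for labs that
#' prefer a robust summary.
#'
#' @param dataset a `ct_dataset` (see [simulate_ct_dataset()]) or a bare
#'   3-d array gene x sample x replicate with `NA` for undetected.
#' @param max_sd replicate-SD threshold in cycles for the QC flag.
#' @param method `"mean"` (default, qPCR convention) or `"median"`.
#' @return list of class `ct_matrix`: `ct` (gene x sample matrix, `NA` =
#'   undetected), `qc_flag` (logical matrix), `n_detected` (integer matrix),
#'   `meta` (carried through when present), `detection_limit`.
#' @export
collapse_replicates <- function(dataset, max_sd = 0.5,
                                method = c("mean", "median")) {
  method <- match.arg(method)
  if (inherits(dataset, "ct_dataset")) {
    arr <- dataset$ct
    meta <- dataset$meta
    limit <- dataset$detection_limit
  } else {
    arr <- dataset
    meta <- NULL
    limit <- NA_real_
  }
  if (!is.array(arr) || length(dim(arr)) != 3) {
    stop("expected a gene x sample x replicate array")
  }
  if (length(arr) == 0) stop("empty Ct dataset")
  fun <- if (method == "mean") mean else stats::median
  ct <- apply(arr, c(1, 2), function(x) {
    d <- x[!is.na(x)]
    if (length(d) == 0) NA_real_ else fun(d)
  })
  repsd <- apply(arr, c(1, 2), function(x) {
    d <- x[!is.na(x)]
    if (length(d) < 2) NA_real_ else sd(d)
  })
  n_det <- apply(arr, c(1, 2), function(x) sum(!is.na(x)))
  structure(
    list(ct = ct,
         qc_flag = !is.na(repsd) & repsd > max_sd,
         replicate_sd = repsd,
         n_detected = n_det,
         meta = meta,
         detection_limit = limit),
    class = "ct_matrix"
  )
}

as_ct_values <- function(x) {
  if (inherits(x, "ct_matrix")) x$ct else x
}

#' Discard genes not detected in every sample
#'
#' A gene is retained only if it is detected (Ct at or below `limit`) in every
#' sample considered; a gene that fails detection in at least one sample is
#' discarded, matching the usual endogenous-control validation rule. A
#' tolerance can be allowed via `max_undetected_frac`.
#'
#' @param matrix collapsed Ct matrix (`ct_matrix` or gene x sample matrix;
#'   `NA` = undetected).
#' @param limit detection limit in cycles (default 40); values above it count
#'   as undetected even if numeric.
#' @param max_undetected_frac fraction of samples allowed to be undetected
#'   before a gene is discarded (default 0 = strict).
#' @param samples optional character vector restricting which samples count
#'   (e.g. cohort samples only, excluding calibrators).
#' @return list: `retained` (gene names), `discarded` (data.frame `gene`,
#'   `sample` naming every offending cell), `ct` (matrix subset to retained
#'   genes).
#' @export
detection_filter <- function(matrix, limit = 40, max_undetected_frac = 0,
                             samples = NULL) {
  ct <- as_ct_values(matrix)
  stopifnot_matrix(ct)
  if (!is.null(samples)) ct <- ct[, samples, drop = FALSE]
  undet <- is.na(ct) | ct > limit
  frac <- rowMeans(undet)
  retained <- rownames(ct)[frac <= max_undetected_frac]
  bad <- which(undet & frac > max_undetected_frac, arr.ind = TRUE)
  discarded <- data.frame(
    gene = rownames(ct)[bad[, 1]],
    sample = colnames(ct)[bad[, 2]],
    stringsAsFactors = FALSE
  )
  discarded <- discarded[!(discarded$gene %in% retained), , drop = FALSE]
  if (length(retained) == 0) {
    warning("detection_filter(): no genes retained")
  }
  full <- as_ct_values(matrix)
  list(retained = retained,
       discarded = discarded[order(discarded$gene, discarded$sample), ,
                             drop = FALSE],
       ct = full[retained, , drop = FALSE])
}

#' Remove between-run offsets using the inter-run calibrator
#'
#' The same pooled calibrator is measured on every run; for each gene the
#' run-specific calibrator Ct, centred on its across-run mean, estimates that
#' run's offset, which is subtracted from every sample of the run.
#' Calibration is per gene because assays have independent efficiencies.
#' Calibrator samples are removed from the output.
#'
#' @param matrix collapsed Ct matrix (`ct_matrix` or gene x sample matrix).
#' @param meta sample metadata with `sample_id`, `run`, `is_calibrator`
#'   (taken from the `ct_matrix` if omitted).
#' @return list: `ct` (calibrated matrix, calibrators dropped), `offsets`
#'   (gene x run matrix of subtracted offsets), `meta` (calibrators dropped).
#' @export
interrun_calibrate <- function(matrix, meta = NULL) {
  ct <- as_ct_values(matrix)
  if (is.null(meta) && inherits(matrix, "ct_matrix")) meta <- matrix$meta
  if (is.null(meta)) stop("sample metadata required for calibration")
  meta <- meta[match(colnames(ct), meta$sample_id), , drop = FALSE]
  runs <- unique(meta$run)
  if (length(runs) <= 1 && !any(meta$is_calibrator)) {
    keep <- !meta$is_calibrator
    return(list(ct = ct[, keep, drop = FALSE],
                offsets = matrix(0, nrow(ct), length(runs),
                                 dimnames = list(rownames(ct), runs)),
                meta = meta[keep, , drop = FALSE]))
  }
  cal_cols <- vapply(runs, function(r) {
    i <- which(meta$run == r & meta$is_calibrator)
    if (length(i) == 0) {
      stop("run '", r, "' has no inter-run calibrator sample")
    }
    i[1]
  }, integer(1))
  cal <- ct[, cal_cols, drop = FALSE]
  colnames(cal) <- as.character(runs)
  if (anyNA(cal)) {
    stop("calibrator undetected for gene(s): ",
         paste(rownames(cal)[apply(is.na(cal), 1, any)], collapse = ", "))
  }
  offsets <- cal - rowMeans(cal)
  keep <- !meta$is_calibrator
  out <- ct
  for (j in which(keep)) {
    out[, j] <- ct[, j] - offsets[, as.character(meta$run[j])]
  }
  list(ct = out[, keep, drop = FALSE],
       offsets = offsets,
       meta = meta[keep, , drop = FALSE])
}

#' Normalize target Ct values to an endogenous control (delta-Ct)
#'
#' `dCt[g, s] = Ct[g, s] - N_s`, where `N_s` is the Ct of the normalizer gene
#' in sample `s`, or the geometric mean of the normalizer Ct values when the
#' control is a multi-gene combination. (Ct is already a log2-scale quantity,
#' so taking the geometric mean of Ct values is a deliberate convention
#' choice, matching how candidate combinations are built, rather than a
#' geometric mean of linear quantities.)
#'
#' @param matrix Ct matrix (`ct_matrix` or gene x sample matrix).
#' @param normalizer character vector of one or more normalizer gene names.
#' @return list of class `normalized_matrix`: `delta_ct` (gene x sample),
#'   `normalizer`, `normalizer_ct` (per-sample `N_s`).
#' @export
#' @examples
#' m <- rbind(target = c(28, 29), ctrlA = c(24, 24), ctrlB = c(26, 26))
#' colnames(m) <- c("s1", "s2")
#' delta_ct(m, c("ctrlA", "ctrlB"))$delta_ct["target", "s1"] # 28 - sqrt(24*26)
delta_ct <- function(matrix, normalizer) {
  ct <- as_ct_values(matrix)
  stopifnot_matrix(ct)
  missing_genes <- setdiff(normalizer, rownames(ct))
  if (length(missing_genes) > 0) {
    stop("normalizer gene(s) not in matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  norm_ct <- ct[normalizer, , drop = FALSE]
  bad <- colnames(ct)[apply(is.na(norm_ct), 2, any)]
  if (length(bad) > 0) {
    stop("normalizer undetected in sample(s): ", paste(bad, collapse = ", "))
  }
  n_s <- apply(norm_ct, 2, geom_mean)
  structure(
    list(delta_ct = sweep(ct, 2, n_s, "-"),
         normalizer = normalizer,
         normalizer_ct = n_s),
    class = "normalized_matrix"
  )
}
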