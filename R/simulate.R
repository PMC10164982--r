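#' Specification for a synthetic qPCR Ct dataset
#'
#' Describes the generative model for replicate-level Ct values:
#' \deqn{Ct_{g,s,r} = baseline_g + a_s + \beta_g I(group_s = tumor) +
#'   \delta_{run(s)} + \epsilon_{g,s,r}}
#' with per-sample effects `a_s ~ N(0, sample_effect_sd)`, per-run offsets
#' `delta`, and replicate noise `epsilon ~ N(0, replicate_sd)`. Values above
#' `detection_limit` are recorded as undetected (`NA`), never as a number.
#' One pooled inter-run calibrator pseudo-sample is added per run; its Ct is
#' the mean gene baseline plus the run offset.
#'
#' @param gene_baselines numeric vector of per-gene baseline Ct (typically
#'   20-35 cycles); names become gene names.
#' @param sample_effect_sd SD (cycles) of the per-sample global effect.
#' @param group_effects per-gene tumor-vs-control shift in cycles (0 for a
#'   stable gene; recycled if scalar). Negative values mean lower Ct (higher
#'   expression) in tumors.
#' @param run_offsets per-run Ct offset in cycles; its length sets the number
#'   of runs. Samples are assigned to runs round-robin.
#' @param replicate_sd replicate noise SD in cycles; scalar or per-gene.
#' @param n_tumor,n_control group sizes (each >= 2).
#' @param n_replicates technical replicates per reaction (default 3).
#' @param detection_limit cycles; must exceed every baseline (default 40).
#' @param dropout_genes gene names forced above the detection limit in at
#'   least one cohort sample.
#' @param seed RNG seed for [simulate_ct_dataset()].
#' @return object of class `ct_sim_spec`.
#' @seealso [simulate_ct_dataset()]
#' @export
ct_sim_spec <- function(gene_baselines,
                        sample_effect_sd = 0.3,
                        group_effects = 0,
                        run_offsets = 0,
                        replicate_sd = 0.2,
                        n_tumor = 30, n_control = 30,
                        n_replicates = 3,
                        detection_limit = 40,
                        dropout_genes = character(),
                        seed = 1L) {
  check_number(gene_baselines, "gene_baselines", lower = 0, strict = TRUE)
  n_genes <- length(gene_baselines)
  if (is.null(names(gene_baselines))) {
    names(gene_baselines) <- sprintf("gene%02d", seq_len(n_genes))
  }
  check_number(sample_effect_sd, "sample_effect_sd", lower = 0)
  check_number(replicate_sd, "replicate_sd", lower = 0)
  check_number(run_offsets, "run_offsets")
  group_effects <- rep_len(group_effects, n_genes)
  replicate_sd <- rep_len(replicate_sd, n_genes)
  if (n_tumor < 2 || n_control < 2) {
    stop("group sizes must be at least 2 (got n_tumor=", n_tumor,
         ", n_control=", n_control, ")")
  }
  if (detection_limit <= max(gene_baselines)) {
    stop("detection_limit must exceed the largest gene baseline")
  }
  if (!all(dropout_genes %in% names(gene_baselines))) {
    stop("dropout_genes must name genes present in gene_baselines")
  }
  structure(
    list(
      gene_baselines = gene_baselines,
      sample_effect_sd = sample_effect_sd,
      group_effects = setNames(group_effects, names(gene_baselines)),
      run_offsets = run_offsets,
      replicate_sd = setNames(replicate_sd, names(gene_baselines)),
      n_tumor = as.integer(n_tumor),
      n_control = as.integer(n_control),
      n_replicates = as.integer(n_replicates),
      detection_limit = detection_limit,
      dropout_genes = dropout_genes,
      seed = as.integer(seed)
    ),
    class = "ct_sim_spec"
  )
}

#' Simulate a replicate-level qPCR Ct dataset
#'
#' Draws Ct values under the model described in [ct_sim_spec()]. The result
#' holds a gene x sample x replicate array (undetected values as `NA`) and a
#' sample metadata table with group, run and inter-run-calibrator flags. The
#' calibrator pseudo-samples (one per run) emulate a pool of all samples
#' measured on every run; their Ct per gene is the mean gene baseline plus
#' the run offset, identical across replicates.
#'
#' @param spec a [ct_sim_spec()].
#' @return object of class `ct_dataset`: list with elements `ct` (3-d array
#'   gene x sample x replicate), `meta` (data.frame with `sample_id`,
#'   `group`, `run`, `is_calibrator`), `detection_limit`, and `truth` (the
#'   spec, for planted-truth checks).
#' @export
#' @examples
#' spec <- ct_sim_spec(c(A = 25, B = 28), n_tumor = 3, n_control = 3,
#'                     sample_effect_sd = 0, replicate_sd = 0)
#' d <- simulate_ct_dataset(spec)
#' d$ct["A", , 1] # all 25
simulate_ct_dataset <- function(spec) {
  stopifnot(inherits(spec, "ct_sim_spec"))
  genes <- names(spec$gene_baselines)
  n_genes <- length(genes)
  n_runs <- length(spec$run_offsets)

  n_cohort <- spec$n_tumor + spec$n_control
  sample_id <- c(sprintf("T%02d", seq_len(spec$n_tumor)),
                 sprintf("C%02d", seq_len(spec$n_control)))
  group <- rep(c("tumor", "control"), c(spec$n_tumor, spec$n_control))
  run <- rep_len(seq_len(n_runs), n_cohort)

  cal_id <- sprintf("IRC_run%d", seq_len(n_runs))
  meta <- data.frame(
    sample_id = c(sample_id, cal_id),
    group = c(group, rep(NA_character_, n_runs)),
    run = c(run, seq_len(n_runs)),
    is_calibrator = c(rep(FALSE, n_cohort), rep(TRUE, n_runs)),
    stringsAsFactors = FALSE
  )

  ct <- with_seed(spec$seed, {
    a <- rnorm(n_cohort, 0, spec$sample_effect_sd)
    arr <- array(
      NA_real_,
      dim = c(n_genes, n_cohort + n_runs, spec$n_replicates),
      dimnames = list(genes, meta$sample_id, NULL)
    )
    is_tumor <- group == "tumor"
    for (g in seq_len(n_genes)) {
      mu <- spec$gene_baselines[g] + a +
        spec$group_effects[g] * is_tumor + spec$run_offsets[run]
      eps <- matrix(rnorm(n_cohort * spec$n_replicates, 0,
                          spec$replicate_sd[g]),
                    n_cohort, spec$n_replicates)
      arr[g, seq_len(n_cohort), ] <- mu + eps
    }
    # calibrator pool: mean baseline + run offset, noise-free
    for (r in seq_len(n_runs)) {
      arr[, n_cohort + r, ] <- mean(spec$gene_baselines) + spec$run_offsets[r]
    }
    # planted dropouts: push one random cohort sample above the limit
    for (g in spec$dropout_genes) {
      s <- sample.int(n_cohort, 1)
      arr[g, s, ] <- spec$detection_limit + 1
    }
    arr
  })
  ct[ct > spec$detection_limit] <- NA_real_

  structure(
    list(ct = ct, meta = meta, detection_limit = spec$detection_limit,
         truth = spec),
    class = "ct_dataset"
  )
}

#' Specification for a synthetic small-RNA-seq count matrix
#'
#' Counts are negative-binomially distributed with mean
#' `base_mean / 1e6 * 2^(log2fc * I(tumor)) * library_size`, i.e. `base_means`
#' are on the reads-per-million (RPM) scale of the control group.
#'
#' @param base_means expected control-group RPM per miRNA; names become
#'   miRNA ids.
#' @param group_log2fc per-miRNA tumor-vs-control log2 fold change
#'   (recycled if scalar).
#' @param dispersion NB dispersion (size = 1/dispersion); must be > 0.
#' @param library_sizes total reads per sample, scalar or per sample
#'   (default 2e6).
#' @param n_tumor,n_control samples per group.
#' @param seed RNG seed.
#' @return object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(base_means,
                           group_log2fc = 0,
                           dispersion = 0.1,
                           library_sizes = 2e6,
                           n_tumor = 5, n_control = 5,
                           seed = 1L) {
  check_number(base_means, "base_means", lower = 0)
  if (is.null(names(base_means))) {
    names(base_means) <- sprintf("miR-%03d", seq_along(base_means))
  }
  check_number(dispersion, "dispersion", lower = 0, strict = TRUE)
  check_number(library_sizes, "library_sizes", lower = 0, strict = TRUE)
  n <- n_tumor + n_control
  structure(
    list(
      base_means = base_means,
      group_log2fc = setNames(rep_len(group_log2fc, length(base_means)),
                              names(base_means)),
      dispersion = dispersion,
      library_sizes = rep_len(library_sizes, n),
      n_tumor = as.integer(n_tumor),
      n_control = as.integer(n_control),
      seed = as.integer(seed)
    ),
    class = "count_sim_spec"
  )
}

#' Simulate a small-RNA-seq count matrix with planted truth
#'
#' @param spec a [count_sim_spec()].
#' @return list with `counts` (miRNA x sample integer matrix), `groups`
#'   (character vector per sample), `library_sizes`, and `truth` (data.frame
#'   `id`, `base_mean`, `log2fc`, `is_de`).
#' @export
simulate_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  n <- spec$n_tumor + spec$n_control
  groups <- rep(c("tumor", "control"), c(spec$n_tumor, spec$n_control))
  ids <- names(spec$base_means)
  mu <- outer(spec$base_means / 1e6, spec$library_sizes) *
    2^outer(spec$group_log2fc, as.numeric(groups == "tumor"))
  counts <- with_seed(spec$seed, {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
           nrow = length(ids),
           dimnames = list(ids, c(sprintf("T%02d", seq_len(spec$n_tumor)),
                                  sprintf("C%02d", seq_len(spec$n_control)))))
  })
  list(
    counts = counts,
    groups = setNames(groups, colnames(counts)),
    library_sizes = setNames(spec$library_sizes, colnames(counts)),
    # "truly differential" means a biologically meaningful shift (2-fold),
    # matching the fold-change convention used downstream; small drifts
    # are part of the null
    truth = data.frame(id = ids,
                       base_mean = unname(spec$base_means),
                       log2fc = unname(spec$group_log2fc),
                       is_de = unname(abs(spec$group_log2fc) >= 1),
                       stringsAsFactors = FALSE)
  )
}

#' Simulate differential-expression result tables from external methods
#'
#' Emulates the output tables of count-based DE methods (edgeR, voom,
#' DESeq2 style) run on the same experiment: each method flags a truly
#' differential miRNA significant with probability `sensitivity` and a null
#' miRNA with probability `1 - specificity`. Adjusted p-values are drawn
#' consistent with the flag so that `padj <= alpha` reproduces it exactly.
#'
#' @param truth truth data.frame from [simulate_count_matrix()] (`id`,
#'   `base_mean`, `log2fc`, `is_de`).
#' @param methods number of mock methods (>= 1); or a character vector of
#'   method names.
#' @param sensitivity,specificity per-method call probabilities in `[0, 1]`
#'   (recycled).
#' @param alpha significance level encoded in the generated `padj`.
#' @param seed RNG seed.
#' @return named list of data.frames with columns `id`, `baseMean`,
#'   `log2FC`, `pvalue`, `padj`, `significant`.
#' @export
simulate_de_tables <- function(truth, methods = 3,
                               sensitivity = 1, specificity = 1,
                               alpha = 0.05, seed = 1L) {
  if (is.numeric(methods)) {
    if (methods < 1) stop("'methods' must be at least 1")
    methods <- sprintf("method%d", seq_len(methods))
  }
  m <- length(methods)
  sensitivity <- rep_len(sensitivity, m)
  specificity <- rep_len(specificity, m)
  if (any(sensitivity < 0 | sensitivity > 1 |
          specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  with_seed(seed, {
    out <- lapply(seq_len(m), function(i) {
      p_call <- ifelse(truth$is_de, sensitivity[i], 1 - specificity[i])
      sig <- runif(nrow(truth)) < p_call
      padj <- ifelse(sig, runif(nrow(truth), 0, alpha),
                     runif(nrow(truth), alpha, 1))
      data.frame(
        id = truth$id,
        baseMean = truth$base_mean,
        log2FC = truth$log2fc + rnorm(nrow(truth), 0, 0.05),
        pvalue = padj * runif(nrow(truth), 0.2, 1),
        padj = padj,
        significant = sig,
        stringsAsFactors = FALSE
      )
    })
    setNames(out, methods)
  })
}
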