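#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow with the conventional
#' defaults: detection limit 40 cycles, minimum base mean 100 (RPM),
#' maximum |log2FC| 2 for normalizer screening, stability-value shortlist
#' threshold 5, CV exclusion threshold 200%, significance level 0.05,
#' minimum fold change 2, panel probability cutoff 0.5.
#'
#' @param seed RNG seed driving every stochastic stage.
#' @param detection_limit Ct detection limit (cycles).
#' @param max_replicate_sd replicate-SD QC threshold (cycles).
#' @param base_min minimum mean RPM for screens and consensus.
#' @param lfc_max maximum |log2FC| for normalizer candidates.
#' @param stability_max stability-value shortlist threshold.
#' @param cv_max CV exclusion threshold (percent).
#' @param p_max significance level for expression calls.
#' @param fc_min minimum |fold change| for expression calls.
#' @param cutoff panel probability cutoff.
#' @param cv_mode CV definition, see [cv_of_candidates()].
#' @param combine_k combination size for pseudo-genes.
#' @param alpha adjusted-p significance level for DE tables.
#' @param top_n normalizer candidates returned by the sequencing screen.
#' @param out_dir optional directory for artifacts; `NULL` keeps results in
#'   memory only.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 7L,
                            detection_limit = 40,
                            max_replicate_sd = 0.5,
                            base_min = 100,
                            lfc_max = 2,
                            stability_max = 5,
                            cv_max = 200,
                            p_max = 0.05,
                            fc_min = 2,
                            cutoff = 0.5,
                            cv_mode = "self-vs-calibrator",
                            combine_k = 2,
                            alpha = 0.05,
                            top_n = 5,
                            out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), detection_limit = detection_limit,
              max_replicate_sd = max_replicate_sd, base_min = base_min,
              lfc_max = lfc_max, stability_max = stability_max,
              cv_max = cv_max, p_max = p_max, fc_min = fc_min,
              cutoff = cutoff, cv_mode = cv_mode,
              combine_k = as.integer(combine_k), alpha = alpha,
              top_n = as.integer(top_n), out_dir = out_dir)
  stopifnot(cfg$detection_limit > 0, cfg$base_min >= 0, cfg$lfc_max >= 0,
            cfg$cv_max >= 0, cfg$p_max > 0, cfg$p_max < 1,
            cfg$fc_min >= 1, cfg$cutoff > 0, cfg$cutoff < 1)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config()` returns a `pipeline_config`; the round trip is
#'   lossless.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Simulate a complete synthetic study
#'
#' Builds the full set of inputs the workflow consumes, with planted ground
#' truth: a replicate-level qPCR Ct dataset holding 8 candidate endogenous
#' controls (two of them stable, i.e. zero tumor-vs-control shift; the rest
#' with planted shifts; one forced above the detection limit to exercise
#' the discard rule) plus 5 target miRNAs with planted fold changes of 4,
#' 4, 1/8, 1 and 1; a negative-binomial count matrix whose miRNAs include
#' the qPCR genes; and three mock differential-expression tables with
#' stated per-method sensitivity/specificity.
#'
#' @param seed RNG seed.
#' @param n_tumor,n_control cohort sizes (default 30 + 30).
#' @param sample_effect_sd,replicate_sd,run_offset_sd noise levels (cycles):
#'   per-sample biological scatter, triplicate noise, and the SD of the
#'   per-run offsets (4 runs).
#' @return list: `ct` (a `ct_dataset`), `ec_genes`, `target_genes`,
#'   `stable_pair` (planted stable candidates), `counts` (see
#'   [simulate_count_matrix()]), `de_tables`, `planted_fc` (named true fold
#'   changes of the targets).
#' @export
simulate_study <- function(seed = 7L, n_tumor = 30, n_control = 30,
                           sample_effect_sd = 1.0, replicate_sd = 0.2,
                           run_offset_sd = 0.5) {
  ec_genes <- sprintf("miR-ref-%02d", 1:8)
  target_genes <- sprintf("miR-tgt-%02d", 1:5)
  stable_pair <- ec_genes[1:2]

  baselines <- setNames(
    c(24, 26, 28.5, 22.5, 29.5, 23.5, 28, 25.5,   # EC candidates
      27, 30, 25, 31, 29),                        # targets
    c(ec_genes, target_genes)
  )
  # tumor-vs-control Ct shifts: stable pair 0; other candidates drift;
  # targets at -log2(FC) for planted FC = 4, 4, 1/8, 1, 1
  planted_fc <- setNames(c(4, 4, 1 / 8, 1, 1), target_genes)
  # the unstable candidates are unstable through elevated per-gene noise
  # alone (no tumor shift): opposite shifts would cancel in a
  # geometric-mean combination, equal shifts would form a mutually
  # consistent block that pairwise statistics reward, and a same-signed
  # average shift is absorbed into the per-sample centering so zero-shift
  # genes would look group-different to the model-based method -- any of
  # these would make the planted stable pair a non-unique ground truth
  group_effects <- setNames(
    c(rep(0, length(ec_genes)), -log2(planted_fc)),
    c(ec_genes, target_genes)
  )
  # stable pair at a 0.45-cycle noise floor (technical + biological); a
  # noise-free pair would make pair-vs-own-member selection non-identifiable
  gene_noise <- setNames(
    c(0.45, 0.45, 1.0, 1.2, 1.5, 0.9, 1.3, 1.1,
      rep(replicate_sd, length(target_genes))),
    c(ec_genes, target_genes)
  )
  run_offsets <- with_seed(seed, rnorm(4, 0, run_offset_sd))

  spec <- ct_sim_spec(
    gene_baselines = baselines,
    sample_effect_sd = sample_effect_sd,
    group_effects = group_effects,
    run_offsets = run_offsets,
    replicate_sd = gene_noise,
    n_tumor = n_tumor, n_control = n_control,
    dropout_genes = ec_genes[5],
    seed = seed + 1L
  )
  ct <- simulate_ct_dataset(spec)

  # counts: the qPCR genes plus a background that behaves like a real
  # miRNome -- a few high-abundance stable species carrying most of the
  # library (so RPM totals are compositionally stable), mid-abundance
  # background miRNAs with small biological drifts plus a handful of
  # strong changers, and silent isoforms for the zero-expression filter
  n_bg <- 47
  bg_ids <- sprintf("miR-bg-%02d", seq_len(n_bg))
  hi_ids <- sprintf("miR-hi-%02d", 1:6)
  zero_ids <- sprintf("miR-zero-%02d", 1:12)
  bg <- with_seed(seed + 2L, {
    lfc <- rnorm(n_bg, 0, 0.3)
    lfc[sample(n_bg, 5)] <- c(2.5, 2.8, -2.5, 3.0, -2.7)
    list(base = exp(runif(n_bg, log(5), log(5000))), lfc = lfc)
  })
  base_means <- setNames(
    c(c(800, 1200, 600, 2000, 60, 900, 1500, 700),      # EC candidates
      c(500, 300, 800, 40, 250),                        # targets
      bg$base,
      c(250e3, 200e3, 150e3, 150e3, 100e3, 100e3),      # dominant species
      rep(0, length(zero_ids))),
    c(ec_genes, target_genes, bg_ids, hi_ids, zero_ids)
  )
  count_lfc <- setNames(
    c(c(0, 0, 0.3, 0.45, 0.6, 0.25, 0.45, 0.35),
      log2(planted_fc),
      bg$lfc,
      rep(0, length(hi_ids)),
      rep(0, length(zero_ids))),
    names(base_means)
  )
  counts <- simulate_count_matrix(count_sim_spec(
    base_means = base_means, group_log2fc = count_lfc,
    dispersion = 0.05, library_sizes = 2e6,
    n_tumor = 8, n_control = 8, seed = seed + 3L
  ))

  de_tables <- simulate_de_tables(
    counts$truth, methods = c("edgeR", "voom", "DESeq2"),
    sensitivity = c(0.95, 0.80, 0.85),
    specificity = c(0.95, 0.995, 0.99),
    seed = seed + 4L
  )

  list(ct = ct, ec_genes = ec_genes, target_genes = target_genes,
       stable_pair = stable_pair, counts = counts, de_tables = de_tables,
       planted_fc = planted_fc)
}

#' Run the full endogenous-control selection and quantification workflow
#'
#' Executes the stages in order: simulate (or accept provided inputs) ->
#' replicate collapsing -> detection filtering -> inter-run calibration ->
#' four stability statistics on the candidate controls and their
#' geometric-mean combinations -> rank aggregation and CV-based selection
#' of the endogenous control -> sequencing-count screening and
#' differential-expression consensus -> 2^-ddCt relative quantification of
#' the targets -> logistic diagnostic panel with ROC evaluation. Every
#' stage failure aborts with the stage name. With the same config (seed
#' included) the report is reproduced identically.
#'
#' @param config a [pipeline_config()].
#' @param study optional input bundle as returned by [simulate_study()];
#'   by default one is simulated from `config$seed`.
#' @return list of class `pipeline_report` (also written as
#'   `report.json` plus TSV artifacts under `config$out_dir` when set):
#'   stage log, filter counts, selected endogenous control, per-target
#'   expression results, and panel metrics.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  study <- stage("simulate", {
    if (is.null(study)) study <- simulate_study(seed = config$seed)
    study
  })
  note("simulate: %d genes x %d samples (qPCR), %d miRNAs (counts)",
       dim(study$ct$ct)[1], dim(study$ct$ct)[2], nrow(study$counts$counts))

  pre <- stage("preprocess", {
    collapsed <- collapse_replicates(study$ct,
                                     max_sd = config$max_replicate_sd)
    cohort <- collapsed$meta$sample_id[!collapsed$meta$is_calibrator]
    det <- detection_filter(collapsed, limit = config$detection_limit,
                            samples = cohort)
    cal <- interrun_calibrate(det$ct, collapsed$meta)
    list(collapsed = collapsed, det = det, cal = cal)
  })
  note("preprocess: %d/%d genes detected in all cohort samples; %d run(s) calibrated",
       length(pre$det$retained), dim(study$ct$ct)[1],
       length(unique(pre$cal$meta$run)))

  ec_retained <- intersect(study$ec_genes, pre$det$retained)
  groups <- pre$cal$meta$group

  sel <- stage("selection", {
    ec_cal <- make_combinations(pre$cal$ct[ec_retained, , drop = FALSE],
                                k = config$combine_k)
    report <- stability_report(ec_cal, groups = groups)
    ranking <- aggregate_ranks(report)
    ec_uncal <- make_combinations(
      pre$det$ct[ec_retained, , drop = FALSE], k = config$combine_k
    )
    cvs <- cv_of_candidates(ec_uncal, pre$collapsed$meta,
                            mode = config$cv_mode)
    list(report = report, ranking = ranking, cvs = cvs,
         result = select_endogenous_control(
           ranking, cvs, cv_max = config$cv_max,
           stability_max = config$stability_max
         ))
  })
  note("selection: '%s' selected from %d candidates (%d excluded by CV > %g%%)",
       sel$result$selected, nrow(sel$result$verdicts),
       sum(sel$result$verdicts$verdict == "excluded"), config$cv_max)

  screen <- stage("screen", {
    expr_f <- expression_filter(study$counts$counts)
    rpm <- rpm_normalize(expr_f$counts)
    ec_screen <- ec_candidate_screen(rpm, study$counts$groups,
                                     base_min = config$base_min,
                                     lfc_max = config$lfc_max,
                                     top_n = config$top_n)
    consensus <- de_consensus(study$de_tables, base_min = config$base_min,
                              alpha = config$alpha)
    list(expr_f = expr_f, rpm = rpm, ec_screen = ec_screen,
         consensus = consensus)
  })
  note("screen: %d/%d miRNAs expressed; DE per method [%s]; consensus %d (%d dropped, base mean < %g)",
       screen$expr_f$n_retained, screen$expr_f$n_input,
       paste(screen$consensus$per_method, collapse = ", "),
       length(screen$consensus$consensus),
       length(screen$consensus$dropped_low_expression), config$base_min)

  expr <- stage("express", {
    normalizer <- strsplit(sel$result$selected, "+", fixed = TRUE)[[1]]
    dct <- delta_ct(pre$cal$ct, normalizer)
    targets <- intersect(study$target_genes, rownames(dct$delta_ct))
    fc <- ddct_fold_change(
      list_subset_normalized(dct, targets), groups
    )
    classify_significance(fc, p_max = config$p_max, fc_min = config$fc_min)
  })
  note("express: %d/%d targets significant (p < %g, |FC| >= %g)",
       sum(expr$significant), nrow(expr), config$p_max, config$fc_min)

  panel <- stage("panel", {
    sig <- expr$gene[expr$significant]
    if (length(sig) == 0) stop("no significant miRNAs to build a panel from")
    ddct <- attr(expr, "ddct")
    features <- t(-ddct[sig, , drop = FALSE])   # log2 relative expression
    fit <- fit_panel(features, groups)
    roc <- roc_curve(fit$scores, groups)
    conf <- confusion_at_cutoff(fit$scores, groups, cutoff = config$cutoff)
    list(fit = fit, roc = roc, confusion = conf, features = sig)
  })
  note("panel: %d-miRNA panel, AUC %.3f, sensitivity %.2f%%, specificity %.2f%%",
       length(panel$features), panel$roc$auc,
       panel$confusion$sensitivity, panel$confusion$specificity)

  report <- list(
    schema = "mirnorm-report/1",
    config = unclass(config)[setdiff(names(config), "out_dir")],
    log = log_lines,
    genes_discarded_by_detection = sort(unique(pre$det$discarded$gene)),
    selected_endogenous_control = sel$result$selected,
    shortlist = sel$result$shortlist,
    verdicts = sel$result$verdicts,
    sequencing_ec_candidates = screen$ec_screen$candidates,
    de_per_method = as.list(screen$consensus$per_method),
    de_consensus = screen$consensus$consensus,
    expression = as.data.frame(expr),
    panel = list(
      features = panel$features,
      coefficients = as.list(panel$fit$coefficients),
      separation = panel$fit$separation,
      auc = panel$roc$auc,
      confusion = as.list(panel$confusion$confusion),
      sensitivity = panel$confusion$sensitivity,
      specificity = panel$confusion$specificity
    )
  )
  class(report) <- c("pipeline_report", "list")

  if (!is.null(config$out_dir)) {
    stage("write", write_report(report, sel, screen, pre, config$out_dir))
  }
  report
}

# subset a normalized_matrix to a set of genes, keeping the class contract
list_subset_normalized <- function(dct, genes) {
  structure(
    list(delta_ct = dct$delta_ct[genes, , drop = FALSE],
         normalizer = dct$normalizer,
         normalizer_ct = dct$normalizer_ct),
    class = "normalized_matrix"
  )
}

write_report <- function(report, sel, screen, pre, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  write_table_tsv(sel$result$verdicts, file.path(out_dir, "verdicts.tsv"))
  write_table_tsv(as.data.frame(sel$report),
                  file.path(out_dir, "stability_report.tsv"))
  write_table_tsv(report$expression, file.path(out_dir, "expression.tsv"))
  write_matrix_tsv(pre$cal$ct, file.path(out_dir, "ct_calibrated.tsv"))
  write_matrix_tsv(screen$rpm, file.path(out_dir, "rpm.tsv"))
  invisible(out_dir)
}
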