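# shared simulation scenarios used by module tests and the acceptance suite

# four candidate genes, one with a planted 2-cycle tumor shift; all four
# stability methods should rank it last
planted_shift_scenario <- function(seed) {
  spec <- ct_sim_spec(
    gene_baselines = c(g1 = 24, g2 = 26, g3 = 28, g4 = 25),
    sample_effect_sd = 0.3,
    group_effects = c(0, 0, 0, 2),
    replicate_sd = 0.2,
    n_tumor = 30, n_control = 30, seed = seed
  )
  collapsed <- collapse_replicates(simulate_ct_dataset(spec))
  cohort_report(collapsed)
}

# two stable genes (0.45-cycle noise floor) among three high-noise genes;
# selection over singles + pairs should pick the stable pair's combination
planted_pair_scenario <- function(seed) {
  spec <- ct_sim_spec(
    gene_baselines = c(A = 23, B = 25, C = 28, D = 30, E = 22),
    sample_effect_sd = 0.3,
    group_effects = 0,
    replicate_sd = c(0.45, 0.45, 1.5, 1.8, 2.2),
    n_tumor = 30, n_control = 30, seed = seed
  )
  collapsed <- collapse_replicates(simulate_ct_dataset(spec))
  cohort <- collapsed$meta$sample_id[!collapsed$meta$is_calibrator]
  groups <- collapsed$meta$group[match(cohort, collapsed$meta$sample_id)]
  ranking <- aggregate_ranks(stability_report(
    make_combinations(collapsed$ct[, cohort], k = 2), groups
  ))
  cvs <- cv_of_candidates(make_combinations(collapsed$ct, k = 2),
                          collapsed$meta)
  select_endogenous_control(ranking, cvs)
}

# collapsed cohort Ct matrix + groups + stability report for a dataset
cohort_report <- function(collapsed) {
  cohort <- collapsed$meta$sample_id[!collapsed$meta$is_calibrator]
  groups <- collapsed$meta$group[match(cohort, collapsed$meta$sample_id)]
  list(ct = collapsed$ct[, cohort],
       groups = groups,
       report = stability_report(collapsed$ct[, cohort], groups))
}

# deterministic small Ct matrix with mild structure for oracle checks
toy_ct <- function(genes = 4, samples = 6, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples, rep(c(24, 27, 30, 25, 28)[1:genes],
                                         samples), 0.8),
              nrow = genes,
              dimnames = list(paste0("g", seq_len(genes)),
                              paste0("s", seq_len(samples))))
  m
}
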