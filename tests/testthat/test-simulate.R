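test_that("noise-free Ct simulation reproduces gene baselines exactly", {
  spec <- ct_sim_spec(
    gene_baselines = c(A = 24, B = 30),
    sample_effect_sd = 0, group_effects = 0, run_offsets = 0,
    replicate_sd = 0, n_tumor = 3, n_control = 3, seed = 11
  )
  d <- simulate_ct_dataset(spec)
  cohort <- d$meta$sample_id[!d$meta$is_calibrator]
  expect_true(all(d$ct["A", cohort, ] == 24))
  expect_true(all(d$ct["B", cohort, ] == 30))
  # calibrator pool sits at the mean baseline
  expect_true(all(d$ct[, "IRC_run1", ] == 27))
})

test_that("Ct simulation is deterministic under a fixed seed", {
  spec <- ct_sim_spec(gene_baselines = c(A = 24, B = 26, C = 29),
                      n_tumor = 5, n_control = 5, seed = 99)
  expect_identical(simulate_ct_dataset(spec), simulate_ct_dataset(spec))
  spec2 <- ct_sim_spec(gene_baselines = c(A = 24, B = 26, C = 29),
                       n_tumor = 5, n_control = 5, seed = 100)
  expect_false(identical(simulate_ct_dataset(spec)$ct,
                         simulate_ct_dataset(spec2)$ct))
})

test_that("ct_sim_spec rejects invalid designs", {
  expect_error(ct_sim_spec(c(A = 24), n_tumor = 1, n_control = 5),
               "at least 2")
  expect_error(ct_sim_spec(c(A = 24), replicate_sd = -1), "at least")
  expect_error(ct_sim_spec(c(A = 45), detection_limit = 40), "exceed")
  expect_error(ct_sim_spec(c(A = 24), dropout_genes = "Z"), "dropout")
})

test_that("dropout genes are recorded as undetected, never numeric", {
  spec <- ct_sim_spec(gene_baselines = c(A = 24, B = 26),
                      dropout_genes = "B", n_tumor = 4, n_control = 4,
                      seed = 3)
  d <- simulate_ct_dataset(spec)
  cohort <- d$meta$sample_id[!d$meta$is_calibrator]
  expect_true(anyNA(d$ct["B", cohort, ]))
  expect_true(all(d$ct[!is.na(d$ct)] <= spec$detection_limit))
})

test_that("planted group-shift gene ranks last in all four stability methods", {
  res <- planted_shift_scenario(seed = 1)$report
  worst <- function(col) res$gene[which.max(res[[col]])]
  expect_equal(worst("genorm_rank"), "g4")
  expect_equal(worst("normfinder_rho"), "g4")
  expect_equal(worst("bestkeeper_sd"), "g4")
  expect_equal(worst("deltact_stability"), "g4")
})

test_that("rank-last recovery strengthens with effect size", {
  rate <- function(beta) {
    mean(vapply(1:25, function(s) {
      spec <- ct_sim_spec(
        gene_baselines = c(g1 = 24, g2 = 26, g3 = 28, g4 = 25),
        sample_effect_sd = 0.3, group_effects = c(0, 0, 0, beta),
        replicate_sd = 0.4, n_tumor = 10, n_control = 10, seed = s
      )
      r <- cohort_report(collapse_replicates(simulate_ct_dataset(spec)))
      r$report$gene[which.max(r$report$deltact_stability)] == "g4"
    }, logical(1)))
  }
  rates <- vapply(c(0.2, 0.8, 2.4), rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.95)
})

test_that("NB count simulation recovers planted base means at low dispersion", {
  # base means cover (nearly) the whole library so realized RPM is on the
  # same scale as the planted values
  spec <- count_sim_spec(
    base_means = c(m1 = 200, m2 = 2000, m3 = 50, rest = 1e6 - 2250),
    group_log2fc = 0, dispersion = 1e-4,
    library_sizes = 5e6, n_tumor = 25, n_control = 25, seed = 8
  )
  sim <- simulate_count_matrix(spec)
  rpm <- rpm_normalize(sim$counts)
  obs <- rowMeans(rpm)
  # mild deviation allowed: RPM renormalizes by the realized library size
  expect_true(all(abs(obs - sim$truth$base_mean) / sim$truth$base_mean < 0.05))
})

test_that("null count simulation shows no group difference", {
  spec <- count_sim_spec(
    base_means = rep(500, 20), group_log2fc = 0, dispersion = 0.05,
    library_sizes = 2e6, n_tumor = 10, n_control = 10, seed = 21
  )
  sim <- simulate_count_matrix(spec)
  rpm <- rpm_normalize(sim$counts)
  ps <- apply(rpm, 1, function(x) {
    t.test(x[sim$groups == "tumor"], x[sim$groups == "control"])$p.value
  })
  # p-values roughly uniform: no excess of small ones
  expect_lt(mean(ps < 0.05), 0.25)
  expect_gt(mean(ps), 0.25)
})

test_that("count simulation is deterministic and validates dispersion", {
  spec <- count_sim_spec(base_means = c(a = 10, b = 100), seed = 5)
  expect_identical(simulate_count_matrix(spec), simulate_count_matrix(spec))
  expect_error(count_sim_spec(base_means = c(a = 10), dispersion = 0),
               "greater than")
})

test_that("perfect DE calls reproduce the planted DE set exactly", {
  truth <- data.frame(id = sprintf("m%02d", 1:30),
                      base_mean = 500, log2fc = rep(c(3, 0), c(12, 18)),
                      is_de = rep(c(TRUE, FALSE), c(12, 18)))
  tabs <- simulate_de_tables(truth, methods = 3, sensitivity = 1,
                             specificity = 1, seed = 2)
  for (tab in tabs) {
    expect_setequal(tab$id[tab$significant], truth$id[truth$is_de])
    expect_true(all((tab$padj <= 0.05) == tab$significant))
  }
  none <- simulate_de_tables(truth, methods = 1, sensitivity = 0,
                             specificity = 1, seed = 2)
  expect_length(none[[1]]$id[none[[1]]$significant], 0)
})

test_that("imperfect DE calls match direct enumeration of generated flags", {
  truth <- data.frame(id = sprintf("m%03d", 1:250),
                      base_mean = 500,
                      log2fc = rep(c(2.5, 0), c(200, 50)),
                      is_de = rep(c(TRUE, FALSE), c(200, 50)))
  tabs <- simulate_de_tables(truth, methods = 3, sensitivity = 0.9,
                             specificity = 1, seed = 77)
  flagged <- lapply(tabs, function(tab) tab$id[tab$significant])
  expected_n <- length(Reduce(intersect, flagged))
  cons <- de_consensus(tabs, base_min = 0)
  expect_length(cons$intersection, expected_n)
  expect_error(simulate_de_tables(truth, methods = 2, sensitivity = 1.4),
               "\\[0, 1\\]")
})
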