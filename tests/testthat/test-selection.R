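test_that("rank aggregation reproduces direct geometric-mean arithmetic", {
  rep <- data.frame(
    gene = c("A", "B", "C", "D", "E"),
    genorm_rank = c(1.5, 1.5, 3, 4, 5),
    normfinder_rho = c(0.1, 0.3, 0.2, 0.5, 0.4),
    bestkeeper_sd = c(0.2, 0.3, 0.4, 0.6, 0.5),
    deltact_stability = c(0.2, 0.4, 0.3, 0.7, 0.6)
  )
  rk <- aggregate_ranks(rep)
  a <- rk[rk$gene == "A", ]
  expect_equal(a$stability_value, (1.5 * 1 * 1 * 1)^(1 / 4))
  # ranks (2, 3, 4, 5) -> (120)^(1/4)
  expect_equal(prod(c(2, 3, 4, 5))^(1 / 4), 3.30975092, tolerance = 1e-8)
  d <- rk[rk$gene == "D", ]
  expect_equal(d$stability_value,
               (4 * rank(rep$normfinder_rho)[4] *
                  rank(rep$bestkeeper_sd)[4] *
                  rank(rep$deltact_stability)[4])^(1 / 4))
  expect_equal(rk$gene[1], "A")
})

test_that("aggregated stability value is invariant to monotone transforms", {
  set.seed(12)
  rep <- data.frame(
    gene = paste0("g", 1:6),
    genorm_rank = c(1.5, 1.5, 3:6),
    normfinder_rho = runif(6),
    bestkeeper_sd = runif(6),
    deltact_stability = runif(6)
  )
  rk1 <- aggregate_ranks(rep)
  rep2 <- rep
  rep2$normfinder_rho <- exp(5 * rep2$normfinder_rho)   # strictly increasing
  rep2$bestkeeper_sd <- rep2$bestkeeper_sd^3 + 1
  rk2 <- aggregate_ranks(rep2)
  expect_equal(rk1$stability_value[match(rep$gene, rk1$gene)],
               rk2$stability_value[match(rep$gene, rk2$gene)])
  # geometric mean of ranks bounded by min and max rank
  rmat <- as.matrix(rk1[, c("genorm", "normfinder", "bestkeeper", "deltact")])
  expect_true(all(rk1$stability_value <= apply(rmat, 1, max) + 1e-12))
  expect_true(all(rk1$stability_value >= apply(rmat, 1, min) - 1e-12))
})

test_that("rank aggregation rejects incomplete reports", {
  rep <- data.frame(gene = c("A", "B"), genorm_rank = c(1.5, 1.5),
                    normfinder_rho = c(0.1, NA),
                    bestkeeper_sd = c(0.2, 0.3),
                    deltact_stability = c(0.2, 0.4))
  expect_error(aggregate_ranks(rep), "B")
  expect_error(aggregate_ranks(rep[, -4]), "bestkeeper_sd")
})

test_that("pseudo-gene combinations are per-sample geometric means", {
  ct <- rbind(A = c(24, 30), B = c(26, 32), C = c(28, 28))
  colnames(ct) <- c("s1", "s2")
  ext <- make_combinations(ct, k = 2)
  expect_equal(nrow(ext), 3 + choose(3, 2))
  expect_equal(ext["A+B", "s1"], sqrt(24 * 26), tolerance = 1e-12)
  expect_equal(ext["A+B", "s2"], sqrt(30 * 32), tolerance = 1e-12)
  # identical members collapse to the member itself
  ct2 <- rbind(X = c(25, 27), Y = c(25, 27))
  colnames(ct2) <- c("s1", "s2")
  expect_equal(unname(make_combinations(ct2, 2)["X+Y", ]),
               unname(ct2["X", ]))
  # C(5, 2) = 10 pairs
  ct5 <- toy_ct(genes = 5, samples = 3)
  expect_equal(nrow(make_combinations(ct5, 2)), 15)
  expect_error(make_combinations(ct, k = 1), "at least 2")
  expect_error(make_combinations(ct, k = 4), "exceeds")
})

test_that("candidate CV matches hand arithmetic and flags CV explosions", {
  # candidate whose dCt over the 3 control samples is {1, 2, 3}
  ct <- rbind(g = c(26, 27, 28, 25))
  colnames(ct) <- c("C1", "C2", "C3", "IRC")
  meta <- data.frame(sample_id = colnames(ct),
                     group = c("control", "control", "control", NA),
                     run = 1, is_calibrator = c(FALSE, FALSE, FALSE, TRUE))
  cv <- cv_of_candidates(ct, meta)
  expect_equal(cv$cv_percent, 50)   # SD 1, |mean| 2
  expect_false(cv$near_zero_mean)

  # dCt {-0.5, 0.5, 0.3}: mean 0.1 -> CV > 200% (the exclusion criterion)
  ct2 <- rbind(g = c(24.5, 25.5, 25.3, 25))
  colnames(ct2) <- colnames(ct)
  cv2 <- cv_of_candidates(ct2, meta)
  expect_gt(cv2$cv_percent, 200)
  expect_equal(cv2$cv_percent, 100 * sd(c(-0.5, 0.5, 0.3)) / 0.1)
  # |mean dCt| below epsilon raises the unstable-by-construction flag
  ct3 <- rbind(g = c(24.96, 25.06, 25.01, 25))
  colnames(ct3) <- colnames(ct)
  expect_true(cv_of_candidates(ct3, meta)$near_zero_mean)

  # constant dCt -> CV 0
  ct3 <- rbind(g = c(27, 27, 27, 25))
  colnames(ct3) <- colnames(ct)
  expect_equal(cv_of_candidates(ct3, meta)$cv_percent, 0)

  expect_error(cv_of_candidates(ct[, c(1, 2, 4)], meta[c(1, 2, 4), ]),
               "at least 3 control")
})

test_that("targets-vs-candidate CV pools target dCt values", {
  ct <- rbind(cand = c(25, 25, 25), t1 = c(27, 28, 27), t2 = c(30, 30, 31))
  colnames(ct) <- paste0("C", 1:3)
  meta <- data.frame(sample_id = colnames(ct), group = "control",
                     run = 1, is_calibrator = FALSE)
  cv <- cv_of_candidates(ct, meta, candidates = "cand",
                         mode = "targets-vs-candidate",
                         targets = c("t1", "t2"))
  pooled <- c(2, 3, 2, 5, 5, 6)
  expect_equal(cv$cv_percent, 100 * sd(pooled) / abs(mean(pooled)))
})

test_that("selection applies CV exclusion then stability, with CV tie-break", {
  rk <- data.frame(gene = c("A", "B", "C"),
                   genorm = c(1.5, 1.5, 3), normfinder = c(1, 2, 3),
                   bestkeeper = c(2, 1, 3), deltact = c(1, 2, 3),
                   stability_value = c(1.6, 1.6, 3))
  cvs <- data.frame(candidate = c("A", "B", "C"),
                    cv_percent = c(31, 90, 20),
                    mean_dct = c(-2, -1, -3), sd_dct = c(0.6, 0.9, 0.6),
                    near_zero_mean = FALSE)
  sel <- select_endogenous_control(rk, cvs)
  expect_equal(sel$selected, "A")    # tie on stability, lower CV wins

  cvs$cv_percent <- c(250, 90, 20)
  expect_equal(select_endogenous_control(rk, cvs)$selected, "B")
  v <- select_endogenous_control(rk, cvs)$verdicts
  expect_equal(v$verdict[v$gene == "A"], "excluded")

  cvs$cv_percent <- c(250, 300, 220)
  expect_error(select_endogenous_control(rk, cvs), "review")

  # single candidate with acceptable CV is selected
  sel1 <- select_endogenous_control(rk[1, ], cvs <- data.frame(
    candidate = "A", cv_percent = 30, mean_dct = -2, sd_dct = 0.6,
    near_zero_mean = FALSE))
  expect_equal(sel1$selected, "A")
})

test_that("selection recovers a planted stable pair among noisy candidates", {
  sel <- planted_pair_scenario(seed = 3)
  expect_equal(sel$selected, "A+B")
  expect_true("A+B" %in% sel$shortlist)
})
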