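# independent brute-force oracles, written against the defining formulas
# and kept free of any package internals

oracle_genorm_m <- function(ct) {
  g <- nrow(ct)
  out <- numeric(g)
  for (j in 1:g) {
    acc <- c()
    for (k in setdiff(1:g, j)) {
      ratio <- ct[j, ] - ct[k, ]
      acc <- c(acc, sqrt(sum((ratio - mean(ratio))^2) / (ncol(ct) - 1)))
    }
    out[j] <- mean(acc)
  }
  setNames(out, rownames(ct))
}

oracle_deltact <- function(ct) {
  g <- nrow(ct)
  out <- numeric(g)
  for (j in 1:g) {
    sds <- c()
    for (k in setdiff(1:g, j)) sds <- c(sds, sd(ct[j, ] - ct[k, ]))
    out[j] <- mean(sds)
  }
  setNames(out, rownames(ct))
}

oracle_bestkeeper <- function(ct) {
  idx <- apply(ct, 2, function(x) prod(x)^(1 / length(x)))
  list(index = idx,
       sd = apply(ct, 1, sd),
       cv = 100 * apply(ct, 1, sd) / apply(ct, 1, mean),
       r = apply(ct, 1, function(x) cor(x, idx)))
}

test_that("geNorm M values match the brute-force pairwise-SD oracle", {
  ct <- toy_ct(genes = 5, samples = 6)
  expect_equal(genorm(ct)$m, oracle_genorm_m(ct), tolerance = 1e-12)
  ct2 <- toy_ct(genes = 3, samples = 4, seed = 7)
  expect_equal(genorm(ct2)$m, oracle_genorm_m(ct2), tolerance = 1e-12)
})

test_that("a constant-ratio pair attains geNorm M of zero and ranks top", {
  set.seed(1)
  base <- rnorm(8, 27, 1.5)
  ct <- rbind(A = base, B = base + 1.0, C = base + rnorm(8, 0, 0.8))
  colnames(ct) <- paste0("s", 1:8)
  res <- genorm(ct)
  # SD(A - B) = 0, so both M values equal SD against C only, and are equal
  expect_equal(res$m[["A"]], res$m[["B"]], tolerance = 1e-12)
  expect_setequal(names(res$rank)[res$rank == 1.5], c("A", "B"))
  expect_equal(res$rank[["C"]], 3)

  # perfectly proportional trio: all M exactly 0
  ct0 <- rbind(A = base, B = base + 1, C = base - 2)
  colnames(ct0) <- paste0("s", 1:8)
  expect_equal(max(genorm(ct0)$m), 0, tolerance = 1e-12)
})

test_that("adding noise to one gene strictly increases its geNorm M", {
  ct <- toy_ct(genes = 4, samples = 30, seed = 5)
  m0 <- genorm(ct)$m[["g1"]]
  worse <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- ct
    noisy["g1", ] <- noisy["g1", ] + rnorm(ncol(ct), 0, 1)
    genorm(noisy)$m[["g1"]] > m0
  }, logical(1))
  expect_true(all(worse))
})

test_that("geNorm V series has length G-2 and responds to an unstable gene", {
  ct <- toy_ct(genes = 5, samples = 10, seed = 9)
  v <- genorm(ct)$v
  expect_equal(v$n, 2:4)
  expect_true(all(v$v >= 0))
})

test_that("BestKeeper statistics match brute-force arithmetic", {
  ct <- rbind(g1 = c(24.1, 25.3, 23.8), g2 = c(30.2, 31.0, 29.9))
  colnames(ct) <- paste0("s", 1:3)
  bk <- bestkeeper(ct)
  orc <- oracle_bestkeeper(ct)
  expect_equal(bk$index, orc$index, tolerance = 1e-12)
  expect_equal(setNames(bk$stats$sd, bk$stats$gene)[rownames(ct)],
               orc$sd, tolerance = 1e-12)
  expect_equal(setNames(bk$stats$cv, bk$stats$gene)[rownames(ct)],
               orc$cv, tolerance = 1e-12)
  expect_equal(setNames(bk$stats$r, bk$stats$gene)[rownames(ct)],
               orc$r, tolerance = 1e-12)
})

test_that("BestKeeper handles constant genes and ignores other genes for SD", {
  ct <- rbind(flat = c(25, 25, 25, 25), var = c(24, 26, 25, 27))
  colnames(ct) <- paste0("s", 1:4)
  bk <- bestkeeper(ct)
  expect_equal(bk$stats$sd[bk$stats$gene == "flat"], 0)
  expect_equal(bk$stats$cv[bk$stats$gene == "flat"], 0)
  expect_true(is.na(bk$stats$r[bk$stats$gene == "flat"]))
  # duplicating a gene leaves its SD unchanged
  ct3 <- rbind(ct, var2 = ct["var", ])
  expect_equal(bestkeeper(ct3)$stats$sd[2], bk$stats$sd[2])
})

test_that("comparative delta-Ct stability matches the brute-force oracle", {
  ct <- toy_ct(genes = 4, samples = 6, seed = 13)
  expect_equal(deltact_stability(ct), oracle_deltact(ct), tolerance = 1e-12)
  # two genes differing by a constant are both perfectly stable
  two <- ct[1:2, ]
  two[2, ] <- two[1, ] + 2.5
  expect_equal(unname(deltact_stability(two)), c(0, 0))
  expect_error(deltact_stability(ct[1, , drop = FALSE]), "at least 2 genes")
})

test_that("stability statistics are invariant to sample permutation and sample shifts", {
  ct <- toy_ct(genes = 5, samples = 8, seed = 31)
  perm <- sample(ncol(ct))
  expect_equal(sort(genorm(ct[, perm])$m), sort(genorm(ct)$m))
  expect_equal(deltact_stability(ct[, perm]), deltact_stability(ct))
  expect_equal(sort(bestkeeper(ct[, perm])$stats$sd),
               sort(bestkeeper(ct)$stats$sd))
  groups <- rep(c("tumor", "control"), each = 4)
  expect_equal(normfinder(ct[, perm], groups[perm])$rho,
               normfinder(ct, groups)$rho)
  # per-sample additive effects cancel in ratio-based methods
  shifted <- sweep(ct, 2, rnorm(ncol(ct), 0, 3), "+")
  expect_equal(genorm(shifted)$m, genorm(ct)$m, tolerance = 1e-9)
  expect_equal(deltact_stability(shifted), deltact_stability(ct),
               tolerance = 1e-9)
})

test_that("NormFinder favors a zero-variance gene among noisy null genes", {
  set.seed(4)
  n <- 20
  groups <- rep(c("tumor", "control"), each = n / 2)
  ct <- rbind(
    stable = rep(25, n),
    n1 = 27 + rnorm(n, 0, 0.8),
    n2 = 29 + rnorm(n, 0, 0.8),
    n3 = 24 + rnorm(n, 0, 0.8)
  )
  colnames(ct) <- paste0("s", 1:n)
  rho <- normfinder(ct, groups)$rho
  expect_equal(names(which.min(rho)), "stable")
})

test_that("NormFinder flags a planted group-effect gene as least stable", {
  hits <- vapply(1:100, function(s) {
    r <- planted_shift_scenario(seed = s)
    names(which.max(normfinder(r$ct, r$groups)$rho)) == "g4"
  }, logical(1))
  expect_gte(sum(hits), 99)
})

test_that("with identical per-group data NormFinder reduces to the group-free ordering", {
  X <- toy_ct(genes = 5, samples = 6, seed = 17)
  ct <- cbind(X, X)
  colnames(ct) <- paste0("s", 1:12)
  groups <- rep(c("tumor", "control"), each = 6)
  nf <- normfinder(ct, groups)
  expect_equal(max(abs(nf$d)), 0, tolerance = 1e-12)
  free <- normfinder(ct, NULL)$rho
  expect_equal(order(nf$rho), order(free))
})

test_that("stability functions reject degenerate inputs", {
  ct <- toy_ct(genes = 3, samples = 4)
  expect_error(genorm(ct[1:2, ]), "at least 3 genes")
  ct_na <- ct; ct_na[1, 1] <- NA
  expect_error(genorm(ct_na), "missing")
  expect_error(normfinder(ct, groups = rep("tumor", 4)), "2 groups")
  expect_error(normfinder(ct, groups = c("tumor", "tumor", "tumor",
                                         "control")),
               "at least 2 samples")
})
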