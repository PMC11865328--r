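test_that("log-composition covariance matches a hand computation", {
  counts <- matrix(c(10L, 20L, 70L,
                     30L, 30L, 40L,
                     50L, 10L, 40L), 3, 3, byrow = TRUE,
                   dimnames = list(paste0("s", 1:3), paste0("g", 1:3)))
  pc <- 0.5
  # spreadsheet-style oracle: explicit per-cell logs then pairwise covariances
  lc <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    lc[i, j] <- log((counts[i, j] + pc) / (sum(counts[i, ]) + 3 * pc))
  }
  oracle <- matrix(NA_real_, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    oracle[a, b] <- sum((lc[, a] - mean(lc[, a])) *
                          (lc[, b] - mean(lc[, b]))) / 2
  }
  expect_equal(unname(log_composition_covariance(counts, pc)), oracle,
               tolerance = 1e-12)
  expect_error(log_composition_covariance(counts[1, , drop = FALSE]),
               "two samples")
  expect_error(log_composition_covariance(cbind(counts, g4 = 0L)),
               "all-zero")
})

test_that("perfectly proportional genera have zero log-ratio variance", {
  set.seed(1)
  other <- matrix(rpois(200 * 3, 40), 200, 3)
  g1 <- rpois(200, 100) + 1L
  counts <- cbind(g1 = g1, g2 = 3L * g1, other)
  colnames(counts) <- paste0("g", 1:5)
  rownames(counts) <- paste0("s", 1:200)
  S <- log_composition_covariance(counts, pseudocount = 1e-9)
  # var(log x1 - log x2) = S11 + S22 - 2 S12 = 0 for proportional pairs
  expect_lt(S[1, 1] + S[2, 2] - 2 * S[1, 2], 1e-10)
})

test_that("cclasso recovers a planted correlation and kills null edges", {
  # null data: identity latent correlation
  coh0 <- null_cohort(n_taxa = 20, n = 1000, seed = 11)
  fit0 <- cclasso(coh0$counts, lambda = 0.05)
  expect_lt(mean(abs(fit0$rho[upper.tri(fit0$rho)])), 0.05)
  # planted rho = 0.6 recovered within 0.15 with the right sign, 20 seeds
  hits <- ok <- logical(20)
  for (s in 1:20) {
    coh <- null_cohort(n_taxa = 30, n = 500,
                       base = one_edge_correlation(30), seed = 100 + s)
    r <- cclasso(coh$counts, lambda = 0.05)$rho[1, 2]
    hits[s] <- r > 0
    ok[s] <- abs(r - 0.6) < 0.15
  }
  expect_gte(sum(hits), 19)
  expect_gte(sum(ok), 19)
})

test_that("a dominating penalty zeroes every off-diagonal entry", {
  coh <- null_cohort(n_taxa = 10, n = 100, base = one_edge_correlation(10),
                     seed = 2)
  fit <- cclasso(coh$counts, lambda = 1e3 * max(abs(
    log_composition_covariance(coh$counts))))
  expect_true(all(fit$Sigma[upper.tri(fit$Sigma)] == 0))
})

test_that("fit invariants hold: symmetry, PSD, monotone objective", {
  for (s in 1:3) {
    coh <- null_cohort(n_taxa = 12, n = 150,
                       base = block_correlation(12, 3, 0.5), seed = 40 + s)
    fit <- cclasso(coh$counts, lambda = 0.03)
    expect_true(isSymmetric(unname(fit$Sigma)))
    expect_equal(unname(diag(fit$rho)), rep(1, 12))
    expect_true(all(abs(fit$rho) <= 1))
    expect_gte(fit$min_eig, -1e-8)
    expect_true(all(diff(fit$objective) <= 1e-8))
  }
})

test_that("genus relabelling permutes the estimate identically", {
  coh <- null_cohort(n_taxa = 8, n = 120,
                     base = block_correlation(8, 4, 0.5), seed = 9)
  fit <- cclasso(coh$counts, lambda = 0.05)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  fit_p <- cclasso(coh$counts[, perm], lambda = 0.05)
  expect_equal(unname(fit_p$rho), unname(fit$rho[perm, perm]),
               tolerance = 1e-6)
})

test_that("estimated sign agrees with the log-ratio variance criterion", {
  # for a 2-taxon system, var(log x1 - log x2) below the independent
  # expectation S11 + S22 implies positive latent association
  for (rho in c(0.7, -0.7)) {
    coh <- null_cohort(n_taxa = 6, n = 800,
                       base = one_edge_correlation(6, rho = rho), seed = 21)
    S <- log_composition_covariance(coh$counts)
    fit <- cclasso(coh$counts, lambda = 0)
    lr_gap <- (S[1, 1] + S[2, 2]) - (S[1, 1] + S[2, 2] - 2 * S[1, 2])
    expect_equal(sign(fit$rho[1, 2]), sign(lr_gap))
    expect_equal(sign(fit$rho[1, 2]), sign(rho))
  }
})

test_that("model methods expose the fit consistently", {
  coh <- null_cohort(n_taxa = 6, n = 100, seed = 3)
  fit <- cclasso(coh$counts, lambda = 0.05)
  expect_s3_class(fit, "cclasso")
  expect_identical(coef(fit), fit$rho)
  expect_identical(coef(fit, "covariance"), fit$Sigma)
  expect_equal(residuals(fit), fit$S - fitted(fit))
  s <- summary(fit)
  expect_s3_class(s, "summary.cclasso")
  expect_equal(s$n_edges, s$n_positive + s$n_negative)
  expect_output(print(fit), "Latent correlation network")
  expect_output(print(s), "CCLasso fit")
})

test_that("cross-validation prefers sparsity on noise and density on signal", {
  grid <- c(0.01, 0.05, 0.2, 0.5, 1)
  upper <- 0
  for (s in 1:10) {
    coh <- null_cohort(n_taxa = 10, n = 60, seed = 300 + s)
    lam <- select_lambda(coh$counts, grid = grid, folds = 3, seed = s)
    upper <- upper + (lam >= 0.2)
  }
  expect_gte(upper, 8) # pure noise: high penalty in at least 80% of seeds
  lower <- 0
  for (s in 1:5) {
    coh <- null_cohort(n_taxa = 8, n = 400,
                       base = block_correlation(8, 4, 0.6), seed = 400 + s)
    lam <- select_lambda(coh$counts, grid = grid, folds = 3, seed = s)
    lower <- lower + (lam <= 0.05)
  }
  expect_gte(lower, 4) # strong dense signal, n >> p: low penalty
  expect_equal(select_lambda(matrix(1:20, 10, 2), grid = 0.07), 0.07)
  expect_error(select_lambda(matrix(1:8, 4, 2), grid = grid, folds = 5),
               "fewer samples")
})

test_that("bootstrap p-values detect planted edges and respect the add-one rule", {
  B <- 59
  hits <- logical(15)
  for (s in 1:15) {
    coh <- null_cohort(n_taxa = 8, n = 300,
                       base = one_edge_correlation(8, rho = 0.7),
                       seed = 500 + s)
    be <- bootstrap_edges(coh$counts, lambda = 0.05, B = B, seed = s)
    e <- be[be$genus_i == "g001" & be$genus_j == "g002", ]
    hits[s] <- e$p_boot <= 0.05
    # an edge whose bootstrap distribution never crosses zero gets 2/(B+1)
    if (s == 1) expect_equal(e$p_boot, 2 / (B + 1))
  }
  expect_gte(sum(hits), 14)
  # size on null edges from a single null stratum
  coh0 <- null_cohort(n_taxa = 8, n = 300, seed = 777)
  be0 <- bootstrap_edges(coh0$counts, lambda = 0.05, B = B, seed = 1)
  expect_lte(mean(be0$p_boot <= 0.05), 0.10)
  expect_error(bootstrap_edges(coh0$counts[1:10, ], B = 10),
               "stratum too small")
})
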