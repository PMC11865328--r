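test_that("Cochran's Q between conditions matches hand algebra", {
  h <- cochran_q_between(c(0.4, -0.4), c(0.1, 0.1))
  expect_equal(h$Q, 32, tolerance = 1e-12)
  expect_equal(h$df, 1L)
  expect_equal(round(h$I2, 1), 96.9)
  # identical effects: no heterogeneity
  same <- cochran_q_between(c(0.25, 0.25), c(0.05, 0.08))
  expect_equal(same$Q, 0, tolerance = 1e-14)
  expect_equal(same$I2, 0)
  expect_equal(same$p, 1)
  # invariance under a global sign flip
  a <- cochran_q_between(c(0.3, 0.1, -0.2), c(0.1, 0.2, 0.15))
  b <- cochran_q_between(-c(0.3, 0.1, -0.2), c(0.1, 0.2, 0.15))
  expect_equal(a, b)
  expect_error(cochran_q_between(0.3, 0.1), "at least two")
  # agrees with the Q computed inside random-effects pooling
  set.seed(7)
  z <- rnorm(6); v <- runif(6, 0.01, 0.05)
  expect_equal(cochran_q_between(z, sqrt(v))$Q, pool_random_effects(z, v)$Q,
               tolerance = 1e-12)
})

test_that("differential edges are classified by sign and magnitude", {
  expect_equal(classify_differential(0.3, 0.1), "increased")
  expect_equal(classify_differential(0.1, 0.3), "decreased")
  expect_equal(classify_differential(0.2, -0.2), "reversed")
  expect_equal(classify_differential(c(-0.5, -0.1), c(-0.2, -0.4)),
               c("increased", "decreased"))
})

test_that("differential network flags planted strength changes", {
  mk_meta <- function(z, se, sig) {
    data.frame(genus_i = sprintf("a%02d", seq_along(z)),
               genus_j = sprintf("b%02d", seq_along(z)),
               pooled_z = z, se = se, significant = sig,
               stringsAsFactors = FALSE)
  }
  z_case <- c(0.8, 0.10, 0.30)
  z_ctrl <- c(0.1, 0.12, 0.30)
  mc <- mk_meta(z_case, rep(0.05, 3), c(TRUE, TRUE, TRUE))
  mn <- mk_meta(z_ctrl, rep(0.05, 3), c(TRUE, TRUE, TRUE))
  d <- differential_network(mc, mn)
  expect_equal(d$heterogeneous, c(TRUE, FALSE, FALSE))
  expect_equal(d$class, c("increased", NA, NA))
  # heterogeneity flag is invariant to swapping condition labels
  d2 <- differential_network(mn, mc)
  expect_equal(d2$heterogeneous, d$heterogeneous)
  expect_equal(d2$Q, d$Q)
  # universe restricted to edges significant in either condition
  mn$significant <- c(FALSE, FALSE, FALSE)
  mc$significant <- c(TRUE, FALSE, FALSE)
  d3 <- differential_network(mc, mn)
  expect_equal(nrow(d3), 1)
})

test_that("partial correlation matches the Schur-complement oracle", {
  # closed-form 3x3 example: all off-diagonals 0.5 gives pcor = 1/3
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  expect_equal(partial_correlation(R)[1, 2], 1 / 3, tolerance = 1e-12)
  expect_equal(unname(partial_correlation(diag(4))), diag(4))
  # independent oracle: partial covariance of (1,2) given the rest via the
  # Schur complement S11 - S12 S22^-1 S21, then renormalized
  set.seed(21)
  for (rep in 1:100) {
    p <- sample(3:8, 1)
    A <- matrix(rnorm(p * p), p)
    R <- cov2cor(crossprod(A) + diag(p))
    P <- partial_correlation(R)
    ij <- sample(p, 2)
    rest <- setdiff(seq_len(p), ij)
    Sc <- R[ij, ij] - R[ij, rest, drop = FALSE] %*%
      solve(R[rest, rest, drop = FALSE], R[rest, ij, drop = FALSE])
    expect_equal(P[ij[1], ij[2]], Sc[1, 2] / sqrt(Sc[1, 1] * Sc[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("covariate adjustment leaves independent covariates harmless", {
  set.seed(31)
  n <- 1000
  x1 <- rnorm(n)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  cov8 <- matrix(rnorm(n * 8), n, 8,
                 dimnames = list(NULL, paste0("c", 1:8)))
  ab <- cbind(gA = x1, gB = x2)
  edges <- data.frame(genus_i = "gA", genus_j = "gB",
                      stringsAsFactors = FALSE)
  adj <- adjust_partial_correlation(edges, list(s1 = ab), list(s1 = cov8))
  expect_equal(adj$s1$r, cor(x1, x2), tolerance = 0.02)
  expect_equal(adj$s1$n, n)
  # adjusted and unadjusted pooled effects are consistent under independence
  raw <- meta_network(list(s1 = data.frame(genus_i = "gA", genus_j = "gB",
                                           r = cor(x1, x2), n = n)),
                      k_min = 1)
  adj_meta <- meta_network(adj, k_min = 1)
  cons <- edge_consistency(raw, adj_meta)
  expect_true(cons$consistent)
})

test_that("adjustment rarely perturbs edges when covariates are independent", {
  set.seed(32)
  n <- 1000
  p <- 10
  C <- block_correlation(p, 2, 0.5)
  X <- matrix(rnorm(n * p), n, p) %*% chol(C)
  colnames(X) <- sprintf("g%02d", 1:p)
  cov8 <- matrix(rnorm(n * 8), n, 8)
  pairs <- t(combn(colnames(X), 2))
  edges <- data.frame(genus_i = pairs[, 1], genus_j = pairs[, 2],
                      stringsAsFactors = FALSE)
  adj <- adjust_partial_correlation(edges, list(s = X), list(s = cov8))
  raw <- data.frame(edges, r = apply(pairs, 1, function(pr)
    cor(X[, pr[1]], X[, pr[2]])), n = n)
  cons <- edge_consistency(meta_network(list(s = raw), k_min = 1),
                           meta_network(adj, k_min = 1))
  expect_lte(mean(!cons$consistent), 0.10)
})

test_that("replication reporting distinguishes real from null replication", {
  p <- 12
  base <- block_correlation(p, 2, 0.6)
  planted <- edge_key(sprintf("g%03d", seq(1, p, 2)),
                      sprintf("g%03d", seq(2, p, 2)))
  planted_rows <- function(out) {
    out$table[edge_key(out$table$genus_i, out$table$genus_j) %in% planted, ]
  }
  # replication drawn from the same generator: planted edges mostly
  # consistent (aggregated over 4 replicate cohorts)
  cons <- repl_frac <- NULL
  pm1 <- NULL
  for (rep in 1:4) {
    primary <- lapply(1:3, function(r)
      stratum_edges(null_cohort(p, 300, base, seed = 1000 * rep + r)$counts,
                    lambda = 0.05))
    names(primary) <- paste0("R", 1:3)
    pm <- meta_network(primary)
    if (rep == 1) pm1 <- pm
    repl <- lapply(1:2, function(r)
      stratum_edges(null_cohort(p, 300, base,
                                seed = 1000 * rep + 100 + r)$counts,
                    lambda = 0.05))
    names(repl) <- paste0("C", 1:2)
    tab <- planted_rows(compare_replication(pm, repl))
    cons <- c(cons, tab$consistent)
    repl_frac <- c(repl_frac, tab$replicated)
  }
  expect_gte(mean(cons), 0.8)
  expect_gte(mean(repl_frac), 0.9)
  # identical "replication" is perfectly consistent
  primary1 <- lapply(1:3, function(r)
    stratum_edges(null_cohort(p, 300, base, seed = 1000 + r)$counts,
                  lambda = 0.05))
  names(primary1) <- paste0("R", 1:3)
  self <- compare_replication(pm1, primary1)
  expect_equal(self$pct_consistent, 100)
  # null replication: planted edges rarely consistent
  repl0 <- lapply(1:2, function(r)
    stratum_edges(null_cohort(p, 300, seed = 900 + r)$counts,
                  lambda = 0.05))
  names(repl0) <- paste0("N", 1:2)
  tab0 <- planted_rows(compare_replication(pm1, repl0))
  expect_lte(mean(tab0$consistent), 0.25)
})
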