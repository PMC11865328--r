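test_that("severity trend is weighted least squares on the grade index", {
  tr <- severity_trend(c(0.1, 0.2, 0.3, 0.4), rep(0.05, 4))
  expect_equal(tr$slope, 0.1, tolerance = 1e-12)
  expect_equal(severity_trend(rep(0.25, 4), rep(0.05, 4))$slope, 0,
               tolerance = 1e-12)
  # reversing the grade order negates the slope
  rev_tr <- severity_trend(c(0.4, 0.3, 0.2, 0.1), rep(0.05, 4))
  expect_equal(rev_tr$slope, -tr$slope, tolerance = 1e-12)
  # weighted slope equals the closed-form WLS solution
  z <- c(0.05, 0.25, 0.28, 0.55); se <- c(0.02, 0.1, 0.05, 0.2)
  w <- 1 / se^2; g <- 0:3
  gw <- sum(w * g) / sum(w); zw <- sum(w * z) / sum(w)
  expect_equal(severity_trend(z, se)$slope,
               sum(w * (g - gw) * (z - zw)) / sum(w * (g - gw)^2),
               tolerance = 1e-12)
  expect_warning(und <- severity_trend(c(0.1, 0.2), c(0.1, 0.1)),
                 "fewer than 3")
  expect_true(is.na(und$slope))
})

test_that("grade networks pool per-region fits and fall back when sparse", {
  base <- one_edge_correlation(8, rho = 0.5)
  coh <- null_cohort(8, 400, base, seed = 42)
  md <- coh$metadata
  md$grade <- rep(0:1, each = 200)
  gn <- grade_networks(coh$counts, md, lambda = 0.05, grades = 0:1,
                       min_stratum_n = 20, mode = "combined")
  expect_named(gn, c("0", "1"))
  # a single grade reduces to the plain pooled network of its samples
  idx <- md$grade == 0
  direct <- meta_network(list(
    combined = stratum_edges(coh$counts[idx, , drop = FALSE], lambda = 0.05)))
  expect_equal(gn[["0"]], direct)
  # grade with no usable stratum errors with its name
  md_bad <- md; md_bad$grade[md_bad$grade == 1] <- 0; md_bad$grade[1:5] <- 1
  expect_error(grade_networks(coh$counts, md_bad, grades = 0:1,
                              mode = "combined"),
               "grade 1")
})

test_that("grade-independent correlations give concordant grade networks", {
  base <- block_correlation(8, 4, 0.5)
  coh <- null_cohort(8, 1600, base, seed = 77)
  md <- coh$metadata
  set.seed(5)
  md$grade <- sample(0:3, nrow(md), replace = TRUE)
  md$region <- rep(c("R1", "R2"), length.out = nrow(md))
  gn <- grade_networks(coh$counts, md, lambda = 0.05, min_stratum_n = 20)
  for (g in c("1", "2", "3")) {
    k0 <- edge_key(gn[["0"]]$genus_i, gn[["0"]]$genus_j)
    kg <- edge_key(gn[[g]]$genus_i, gn[[g]]$genus_j)
    shared <- intersect(k0, kg)
    dz <- gn[["0"]]$pooled_z[match(shared, k0)] -
      gn[[g]]$pooled_z[match(shared, kg)]
    expect_lt(median(abs(dz)), 0.1)
  }
})

test_that("severity funnel flags planted grade-dependent edges", {
  # planted slope 0.15/grade on edge (1,2); grade-constant block elsewhere
  cfg <- sim_config(
    n_taxa = 8, n_regions = 2, samples_per_region = 600,
    grade_proportions = rep(0.25, 4),
    base_correlation = block_correlation(8, 2, 0.3),
    differential_edges = empty_differential(),
    severity_edges = data.frame(i = 1, j = 2, rho_slope_per_grade = 0.15),
    pathway_effects = empty_pathways(), n_pathways = 2,
    region_jitter_sd = 0, seed = 31)
  coh <- simulate_cohort(cfg)
  gn <- grade_networks(coh$counts, coh$metadata, lambda = 0.03,
                       min_stratum_n = 20)
  cand <- data.frame(genus_i = c("g001", "g003"), genus_j = c("g002", "g004"),
                     stringsAsFactors = FALSE)
  sev <- severity_edges(cand, gn)
  expect_true(sev$grade_heterogeneous[1])
  expect_true(sev$severity_associated[1])
  expect_gt(sev$slope[1], 0)
  expect_false(isTRUE(sev$severity_associated[2]))
  # pooled strength increases monotonically for the planted edge
  zs <- as.numeric(sev[1, paste0("z_g", 0:3)])
  expect_true(all(diff(zs) > 0))
})

test_that("rank-based group tests match brute-force statistics on tiny data", {
  # Wilcoxon rank-sum W equals the count of pairs won (minus ties/2)
  x <- c(1.2, 3.4, 2.2); y <- c(0.3, 2.8, 4.1, 0.9)
  w_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(unname(wilcox.test(x, y, exact = FALSE)$statistic), w_brute)
  # Kruskal-Wallis H from the rank-sum definition
  g <- rep(1:2, c(3, 4)); v <- c(x, y)
  r <- rank(v); N <- length(v)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  expect_equal(unname(kruskal.test(v, g)$statistic), H, tolerance = 1e-12)
})

test_that("differential abundance detects planted shifts and keeps size", {
  set.seed(61)
  n <- 600
  md <- data.frame(
    grade = sample(0:3, n, replace = TRUE),
    age = rnorm(n, 53, 15), sex = rbinom(n, 1, 0.5),
    bmi = rnorm(n, 23, 3), smoking = rbinom(n, 1, 0.3),
    antibiotics = rbinom(n, 1, 0.1), diabetes = rbinom(n, 1, 0.1),
    hypercholesterolemia = rbinom(n, 1, 0.15), obesity = rbinom(n, 1, 0.1))
  md$hypertension <- md$grade >= 1
  feats <- cbind(
    shifted = rnorm(n) + 0.5 * md$hypertension,  # planted group shift
    trended = rnorm(n) + 0.25 * md$grade,        # planted grade trend
    null1 = rnorm(n), null2 = rnorm(n), constant = rep(1, n))
  two <- differential_abundance(feats, md, "two_group")
  expect_lt(two$q[two$feature == "shifted"], 0.05)
  expect_equal(two$p[two$feature == "constant"], 1)
  four <- differential_abundance(feats, md, "four_grade")
  expect_lt(four$q[four$feature == "trended"], 0.05)
  expect_lt(four$spearman_q[four$feature == "trended"], 0.05)
  expect_gt(four$spearman_rho[four$feature == "trended"], 0)
  # copied groups (identical data in both): no signal
  md2 <- rbind(md[1:(n / 2), ], md[1:(n / 2), ])
  md2$hypertension <- rep(c(TRUE, FALSE), each = n / 2)
  feats2 <- rbind(feats[1:(n / 2), ], feats[1:(n / 2), ])
  same <- differential_abundance(feats2, md2, "two_group")
  expect_true(all(same$p[!same$constant] > 0.9))
  # permuted labels keep the test size near nominal
  set.seed(62)
  nulls <- replicate(40, {
    md$hypertension <- sample(md$hypertension)
    differential_abundance(feats[, "shifted", drop = FALSE], md,
                           "two_group")$p
  })
  expect_lte(mean(nulls < 0.05), 0.15)
})
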