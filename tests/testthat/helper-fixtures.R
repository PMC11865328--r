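# Small synthetic fixtures built in code; all sizes kept modest so the suite
# stays fast while still exercising the estimators end to end.

# Single-stratum cohort with an explicit latent correlation matrix and no
# planted differential/severity/pathway structure.
null_cohort <- function(n_taxa = 10, n = 200, base = diag(n_taxa), seed = 1,
                        jitter = 0) {
  cfg <- sim_config(
    n_taxa = n_taxa, n_regions = 1, samples_per_region = n,
    grade_proportions = c(1, 0, 0, 0), base_correlation = base,
    differential_edges = empty_differential(),
    severity_edges = empty_severity(),
    pathway_effects = empty_pathways(),
    n_pathways = 2, region_jitter_sd = jitter, seed = seed)
  simulate_cohort(cfg)
}

empty_differential <- function() {
  data.frame(i = integer(), j = integer(), rho_control = numeric(),
             rho_case = numeric(), class = character(),
             stringsAsFactors = FALSE)
}

empty_severity <- function() {
  data.frame(i = integer(), j = integer(), rho_slope_per_grade = numeric())
}

empty_pathways <- function() {
  data.frame(pathway = character(), i = integer(), j = integer(),
             beta1 = numeric(), beta2 = numeric(), gamma0 = numeric(),
             gamma_slope_per_grade = numeric(), noise_sd = numeric(),
             stringsAsFactors = FALSE)
}

# Correlation matrix with one planted off-diagonal entry.
one_edge_correlation <- function(p, i = 1, j = 2, rho = 0.6) {
  C <- diag(p)
  C[i, j] <- C[j, i] <- rho
  C
}

# Per-stratum edge table built directly from given correlations (bypassing
# the estimator) for meta-analysis unit tests.
edges_from_r <- function(r, n, ids = NULL) {
  k <- length(r)
  ids <- ids %||% sprintf("g%02d", seq_len(2 * k))
  data.frame(genus_i = ids[seq_len(k) * 2 - 1], genus_j = ids[seq_len(k) * 2],
             r = r, n = n, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force BH step-up q-values straight from the definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[o] >= p[o][i])
    q[o[i]] <- min(pmin(p[o][js] * m / js, 1))
  }
  q
}
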