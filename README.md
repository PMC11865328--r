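# coabnet

Differential microbial co-abundance network analysis for region-stratified
compositional cohorts.

Gut microbiome studies of disease usually ask which taxa change in
*abundance*. `coabnet` targets the complementary question: which pairwise
**co-abundances** — correlated abundance patterns between two genera, used as
a proxy for ecological interaction — differ between clinical groups, and
whether their strength tracks disease severity. The package was built around
the hypertension setting (hypertensive vs non-hypertensive participants,
severity grades 0–3 from blood pressure), but every stage is generic. It is
aimed at microbiome statisticians and epidemiologists working with
genus-level 16S count tables plus sample metadata from multi-site cohorts.

## The model

Microbiome profiles are compositional: only relative abundances are observed,
so naive correlations of proportions are biased by the sum constraint.
`coabnet` estimates correlations of *latent* log absolute abundances. Writing
`S` for the sample covariance of log-compositions, the estimator solves

    minimize_{Sigma >= 0, b}  1/2 || S - Sigma + b 1' + 1 b' ||_F^2
                              + lambda * sum_{i<j} |Sigma_ij|

where `b` absorbs the per-sample compositional closure term, the L1 penalty
induces a sparse latent covariance `Sigma`, and `Sigma >= 0` is a
positive-semidefinite constraint (a CCLasso-type penalized least-squares
problem, solved by alternating a closed-form `b` update with an ADMM split of
the soft-threshold and PSD-projection steps). The latent correlation matrix
`rho_ij = Sigma_ij / sqrt(Sigma_ii Sigma_jj)` is the per-stratum network.

The downstream pipeline mirrors standard meta-analytic practice:

1. **Per-stratum networks** — one fit per region × group (optionally with
   bootstrap standard errors as QC).
2. **Random-effects meta-analysis** — per edge, Fisher-z transform
   `z = atanh(r)` with variance `1/(n-3)`, DerSimonian–Laird pooling across
   regions, BH FDR across all genus pairs.
3. **Differential edges** — Cochran's Q between the two groups' pooled
   effects; edges with `I² > 75%` and `p < 0.05` are heterogeneous and
   classified as increased / decreased / reversed.
4. **Covariate adjustment** — partial correlations of each edge given eight
   covariates (age, sex, BMI, smoking, antibiotics, diabetes,
   hypercholesterolemia, obesity), re-pooled and compared via Q.
5. **Severity** — per-grade networks, heterogeneity across the four grades,
   and a weighted linear trend of edge strength on grade.
6. **Pathway interaction variance** — for severity-related genus pairs and
   differential pathways, nested regressions
   `Y ~ x1 + x2` vs `Y ~ x1 + x2 + x1:x2` quantify the extra pathway
   variance `ΔR²` explained by the pair's interaction, with a partial F-test
   and a trend of `ΔR²` on grade.

A synthetic cohort generator (`sim_config()` / `simulate_cohort()`) draws
multinomial counts over a softmax of latent multivariate-normal log
abundances with planted group-, grade- and pathway-level structure, and
returns the full ground truth, so every stage is testable without cohort
data.

## Worked example

```r
library(coabnet)

sim <- sim_config(
  n_taxa = 15, n_regions = 3, samples_per_region = 700, n_pathways = 8,
  base_correlation = block_correlation(15, 3, 0.35),
  differential_edges = data.frame(
    i = c(1, 4, 7, 2), j = c(6, 9, 12, 5),
    rho_control = c(0.05, 0.05, 0.45, 0.25),
    rho_case    = c(0.50, 0.50, 0.10, -0.25),
    class = c("increased", "increased", "decreased", "reversed")),
  severity_edges = data.frame(i = c(3, 10), j = c(13, 15),
                              rho_slope_per_grade = 0.2),
  pathway_effects = data.frame(pathway = c("PWY001", "PWY002"),
                               i = c(3, 10), j = c(13, 15),
                               beta1 = 0.4, beta2 = 0.4, gamma0 = 0.2,
                               gamma_slope_per_grade = 0.4, noise_sd = 0.8),
  seed = 11)
cohort <- simulate_cohort(sim)
cohort
#> Synthetic microbiome cohort
#>   2100 samples x 15 genera, 3 regions, 8 pathways
#>   grade counts: 0=1425, 1=448, 2=153, 3=74

# one stratum: latent correlation network from compositional counts
idx <- cohort$metadata$region == "R01" & !cohort$metadata$hypertension
fit <- cclasso(cohort$counts[idx, ], lambda = 0.05)
fit
#> Latent correlation network (CCLasso-type penalized covariance)
#>   15 taxa, n = 479, lambda = 0.05
#>   39 / 105 nonzero off-diagonal entries; converged in 29 iterations
round(coef(fit)[1:4, 1:4], 2)
#>      g001 g002 g003 g004
#> g001 1.00 0.30 0.24    0
#> g002 0.30 1.00 0.31    0
#> g003 0.24 0.31 1.00    0
#> g004 0.00 0.00 0.00    1

cfg <- pipeline_config(sim = sim, out_dir = tempfile("demo_"),
                       bootstrap_B = 0, seed = 1)
report <- run_pipeline(cfg)
report
#> Co-abundance pipeline report
#>   2100 samples x 15 genera (lambda = 0.05, seed 1)
#>   significant edges: case 21, control 17, union 21
#>   differential edges: 7 (decreased 28.6%, increased 42.9%, reversed 28.6%)
#>   grade-heterogeneous: 6; severity-associated: 2
#>   screened pathways: 2; interaction F-tests: 16 (8 at FDR); trend-significant: 1
```

The first block of the matrix (taxa g001–g003 share a planted block at
correlation 0.35) is recovered at 0.24–0.31 — soft-thresholding shrinks
estimates slightly toward zero — while unrelated pairs are exactly zero. In
the report, the two severity-associated edges are the planted grade-trending
pairs, the two screened pathways are the planted ones, and the significant
extra-variance trend is the planted pathway × pair combination whose
interaction coefficient grows with grade. Every stage also writes its table
(TSV; networks additionally as GraphML) into `out_dir`.

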