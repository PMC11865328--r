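---
title: "Methods: differential co-abundance network meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-abundance network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coabnet)
```

`coabnet` infers pairwise co-abundance networks from compositional microbiome
counts, pools them across study regions, and tests how edges differ between
clinical conditions and across hypertension severity grades. This vignette is
the package's account of the statistical machinery: the models, the knobs
that matter, the numerical choices, and what the synthetic test bed does and
does not establish.

## Latent-correlation estimation from compositions

Sequencing yields relative abundances: each sample's counts are a multinomial
draw over a composition, so correlations computed directly on proportions (or
log-proportions) are distorted by the sum constraint. The estimator therefore
targets the covariance of *latent log absolute abundances*. If `x` is the
latent log-abundance vector with covariance `Sigma`, the observed
log-composition is `x - log(sum(exp(x)))`: each sample's log-composition
differs from its latent value by a shared scalar. Consequently the observed
covariance satisfies approximately `S = Sigma - b 1' - 1 b'` for a nuisance
vector `b`, and `cclasso()` solves

$$
\min_{\Sigma \succeq 0,\; b}\; \tfrac12\,\lVert S - \Sigma + b\mathbf 1^\top
+ \mathbf 1 b^\top\rVert_F^2 \;+\; \lambda \sum_{i<j}\lvert\Sigma_{ij}\rvert .
$$

Assumptions worth keeping in mind: the latent log abundances are taken to be
multivariate normal (so the sample covariance of log-compositions is a
sufficient summary), counts are deep enough that the pseudocounted
log-composition is a reasonable proxy (multinomial resampling noise
*attenuates* correlations; at depths around 10,000+ the attenuation is mild),
and sparsity of the latent correlation matrix is a modelling choice, not a
fact about the data.

### Algorithm and numerical choices

The objective is jointly convex in `(Sigma, b)` and is solved by block
coordinate descent:

* **`b` update** (closed form): with `D = Sigma - S`,
  `b = (D 1 - s 1)/p` where `s = 1' D 1 / (2p)`; this is the exact minimizer
  of the quadratic in `b`.
* **`Sigma` update**: the subproblem
  `min_{Sigma >= 0} 1/2 ||A - Sigma||_F^2 + lambda ||offdiag(Sigma)||_1`
  (with `A = S + b1' + 1b'`) is solved by ADMM, splitting the L1 proximal
  step (soft-thresholding off-diagonals at `lambda/mu`) from the projection
  onto the PSD cone (eigenvalue clipping at zero), with standard
  residual-balancing adaptation of the augmented-Lagrangian parameter `mu`
  (default 1).

Because each block is minimized exactly (the inner ADMM runs to a tolerance
two orders below the outer one), the objective is non-increasing across outer
iterations; the test suite asserts this on every fit. A Sigma-block update
that would *increase* the objective — possible only through finite inner
tolerance — is retried at a tighter tolerance and otherwise rejected, ending
the iteration at the current point.

Further numerical decisions:

* **Reported `Sigma`** is the soft-threshold variable, so entries killed by
  the penalty are *exactly* zero (a dominating penalty empties the whole
  off-diagonal). If the ADMM split leaves a marginally negative eigenvalue,
  a minimal diagonal ridge (the absolute smallest eigenvalue plus 1e-12) is
  added; this preserves the zero pattern and symmetry and keeps the
  covariance PSD to within 1e-8 — the invariant the tests check.
* **Convergence**: relative change of `Sigma` and of the objective below
  `tol` (default 1e-6), outer cap `max_iter = 500`. The problem is convex,
  so restarting is pointless; an unconverged fit carries
  `converged = FALSE` and a warning.
* **Pseudocount** 0.5 counts (standard compositional practice,
  configurable) before forming `log((count + pc)/(depth + p*pc))`.
* **Penalty `lambda`**: the cohort study this package models does not state
  one. The default 0.05 suits log-scale covariances of order one: large
  enough to zero sampling noise of size `O(1/sqrt(n))` for `n` in the
  hundreds, small enough that a planted correlation of 0.6 is shrunk by
  only about its own value. `select_lambda()` offers K-fold (default 5)
  cross-validation on the held-out Frobenius loss of the fitted
  `Sigma - b1' - 1b'`, with ties broken toward the sparser (larger)
  penalty.
* **Bootstrap** (`bootstrap_edges()`): `B = 100` with-replacement resamples
  by default, an add-one sign-based two-sided p-value
  `2 min(#{r* <= 0}+1, #{r* >= 0}+1)/(B+1)`, and the penalty held fixed at
  the full-data choice — re-selection per resample would be slow and adds
  variance. Strata below 20 samples are refused (configurable floor).
  The phrase "iterations" in descriptions of such estimators is sometimes
  read as restarts of the procedure; since the problem is convex, restarts
  cannot change the optimum, so the package exposes only the iteration cap
  and the bootstrap count.

## Meta-analysis and differential edges

Per-stratum correlations are pooled on the Fisher-z scale, `z = atanh(r)`,
with within-stratum variance `1/(n-3)` — the classical correlation
meta-analysis convention; bootstrap standard errors are carried only as QC.
`pool_random_effects()` implements DerSimonian–Laird: the moment estimator
`tau^2 = max(0, (Q - (K-1))/(sum w - sum w^2 / sum w))` with fixed weights
`w = 1/v`, then random-effects weights `1/(v + tau^2)`. DL (rather than
REML) is the classical default of this approach and reproduces hand-checkable
algebra exactly; the tests verify it against an independent implementation.
BH FDR is applied jointly across all pooled genus pairs, separately within
each condition's network. Edges are pooled when estimable in at least two
strata (`k_min`, configurable; a single-stratum input degrades gracefully to
a per-edge z-test).

Differential edges between conditions use Cochran's Q on the two pooled
effects with their pooled standard errors; `I^2 = max(0,(Q-df)/Q)*100`.
The default thresholds — `I^2 > 75` and `p < 0.05` — follow the convention
for "considerable" heterogeneity. The test universe is the union of edges
significant in either condition (the choice is exposed; the alternative
`"all"` is used when measuring error rates against planted truth).
Classification is by sign and magnitude of the pooled z: opposite signs are
`reversed`; otherwise `|z_case| > |z_control|` is `increased`, else
`decreased`. Because per-stratum estimates from a penalized estimator are
slightly noisier than the nominal `1/(n-3)` variance, the Q test's size on
null edges runs near, not strictly at, its nominal level — the acceptance
measurements quantify this on planted-truth cohorts.

Covariate adjustment computes, per stratum and edge, the partial correlation
of the two genera given the eight covariates from the inverse of their joint
correlation matrix (`-Omega_ij / sqrt(Omega_ii Omega_jj)`); a singular matrix
is lifted by a 1e-8 diagonal ridge with a message. Adjusted estimates are
re-pooled and compared to the unadjusted pooled effects with the same Q test
(consistent if `p > 0.05`). Adjustment is per-region-then-pool, for symmetry
with the main pipeline. Replication against external cohorts pools the
replication strata with the same machinery, then reports per-edge
significance-with-same-sign ("replicated") and Q-consistency.

## Severity grades and trends

Grades follow the clinical bands: grade 1 at SBP in [140,160) or DBP in
[90,100), grade 2 at [160,180) or [100,110), grade 3 at SBP ≥ 180 or
DBP ≥ 110 (mmHg). When the two pressures disagree the maximum applies — the
printed band edges ("140–159") are integer shorthand for half-open real
intervals, and the max rule is the clinical convention. `assign_grade()` is
monotone in each pressure by construction.

Per-grade networks are fitted per region and pooled exactly like the
condition networks. Grades 2–3 are small per region, so strata below the
floor (default 20) are dropped; when a grade retains no stratum the package
falls back to a single combined fit across regions for that grade (an
explicit `mode = "combined"` is also available). Heterogeneity across the
four grade networks uses Q with df = 3; the strength trend is weighted least
squares of pooled z on the numeric grade score 0–3 (equal spacing), weighted
by `1/se^2` because the pooled effects are heteroscedastic — an unweighted
mode exists. The candidate funnel mirrors the study design: differential
edges, then grade-heterogeneous edges, then trend `p < 0.05`; all thresholds
are arguments.

Differential abundance of genera and pathways applies an inverse-rank
transformation `qnorm((rank - 0.5)/n)` (average ranks at ties; the 0.5
offset is the simplest convention, configurable; constant features map to
zeros with a warning) followed by OLS residualization on the eight
covariates, then Wilcoxon rank-sum (two groups) or Kruskal–Wallis plus a
Spearman grade trend (four grades), with BH FDR per feature family.

## Interaction extra variance

For a pathway `Y` and genus pair `(x1, x2)` — all inverse-rank transformed
and covariate-residualized once, globally, before any stratification — the
nested models

$$ Y = \alpha + \beta_1 x_1 + \beta_2 x_2 + \varepsilon
\qquad\text{vs.}\qquad
Y = \alpha + \beta_1 x_1 + \beta_2 x_2 + \beta_{12} x_1 x_2 + \varepsilon $$

are fitted within each grade stratum; `ΔR² = R²_full - R²_reduced ≥ 0` is the
extra pathway variance attributable to the interaction, tested by the partial
F statistic `ΔR²(n-4)/(1-R²_full)` on (1, n-4) df. BH FDR is applied jointly
across all pathway × pair × grade F-tests — the conservative reading when no
family is specified. The trend of `ΔR²` on grade is unweighted OLS: only four
points, and `ΔR²` has no natural standard error here. Near-collinear pairs
(|r| > 0.999) are flagged and skipped; strata under 10 samples are refused.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a 14-region hypertension
cohort: grade proportions 4644:1425:581:259 (grade 0 non-hypertensive),
about 494 participants per region by default, counts drawn as
`Multinomial(depth, softmax(latent))` with log-normal depths
(meanlog `log 30000`, sdlog 0.3), blood pressure uniform within the assigned
grade's band with the non-driving measure kept in its grade-0 range (so
grades round-trip through `assign_grade()` exactly), and covariates from
cohort-level distributions — age N(53, 15), BMI N(23.4, 3.5), 55% female,
33% smokers, with the remaining binaries at plausible configurable rates,
independent of the microbiome by default so covariate adjustment is testable
under a known null. Latent log abundances are multivariate normal — exactly
the structure the estimator assumes — with a block base correlation
(blocks of 4 at 0.45 by default), group-dependent planted edges, severity
edges whose correlation grows linearly per grade (clipped at ±0.9), and
per-region symmetric jitter (sd 0.02) redrawn until the matrix stays positive
definite (minimum eigenvalue above 1e-6; a non-positive-definite *base*
matrix is rejected up front with the offending leading block named). Taxa are
assigned to eight phyla with a Firmicutes-heavy weighting (58%). Pathways
follow `Y = β1 x1 + β2 x2 + γ(grade) x1 x2 + ε` for planted rows and pure
noise otherwise. The full ground truth — per-(region, grade) correlation
matrices, planted edge lists, pathway coefficients, per-sample latent values
— is returned as a manifest that serializes losslessly to JSON.

The per-region sample sizes per grade are not dictated by any published
table; they are exposed as configuration rather than guessed.

What the generator does *not* emulate: phylogenetic structure, taxon-specific
overdispersion beyond the multinomial, zero-inflation mechanisms other than
sampling zeros, covariate–microbiome confounding (unless planted), or
longitudinal sampling. Passing tests therefore demonstrate correctness of
the estimators under the model they assume plus multinomial compositional
distortion — not robustness to every feature of real 16S data.

## Problem sizes and determinism

The test and acceptance runs use scaled-down cohorts chosen as the smallest
sizes at which the planted effects are comfortably identifiable: recovery of
±0.6 latent blocks at p = 30 genera and n = 500 samples; differential
detection with 14 regions × ~200 samples per group and a planted Fisher-z
shift of 0.8 on 10 of 435 pairs; interaction-trend recovery at 300 samples
per grade with γ(g) = 0.1 + 0.2g; and an end-to-end pipeline on 3 regions ×
700 participants with 15 genera. Every stochastic stage takes an explicit
seed, stage seeds are derived from the pipeline seed, and rerunning an
identical configuration produces bit-identical output files (numeric TSVs
are written at 17 significant digits).

## Known limitations

* The Fisher-z variance `1/(n-3)` understates the sampling variability of a
  penalized, thresholded estimator; heterogeneity tests built on it are
  mildly anticonservative on null edges and the bootstrap SEs are the honest
  (but slower) alternative.
* Soft-thresholding biases surviving correlations toward zero by roughly
  `lambda`; pooled effect sizes inherit that bias. Comparisons between
  conditions are less affected because both arms share it.
* DL `tau^2` is truncated at zero and noisy for few strata; with K = 2
  conditions the Q test has a single degree of freedom and limited power for
  small strength differences.
* The interaction `ΔR²` is an in-sample quantity; its grade trend is
  descriptive (four points, unweighted OLS), not an inferential dose-response
  model.
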