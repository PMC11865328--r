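#' Configuration for the synthetic cohort generator
#'
#' Defines a region-stratified compositional cohort with planted co-abundance
#' structure. Defaults emulate the multi-regional hypertension cohort the
#' pipeline targets: 14 regions, hypertension grades in proportions
#' 4644:1425:581:259 (grade 0 = non-hypertensive), roughly 494 participants
#' per region (6916 in total), genus counts drawn as multinomials over a
#' softmax of latent multivariate-normal log abundances, eight covariates with
#' cohort-level distributions (age N(53, 15), BMI N(23.4, 3.5), 55% female,
#' 33% smokers), and pathway abundances with genus-pair interaction effects
#' that scale with grade.
#'
#' @param n_taxa Number of genera, default 60.
#' @param n_regions Number of regions, default 14.
#' @param samples_per_region Participants per region, default 494.
#' @param grade_proportions Four fractions (grades 0-3) summing to 1; default
#'   proportional to 4644:1425:581:259.
#' @param base_correlation Base latent correlation matrix (default
#'   \code{block_correlation(n_taxa, 4, 0.45)}); must be positive definite.
#' @param differential_edges Data frame (i, j, rho_control, rho_case, class)
#'   of edges whose correlation differs between grade 0 and grades >= 1.
#' @param severity_edges Data frame (i, j, rho_slope_per_grade) of edges whose
#'   correlation increases linearly with grade.
#' @param region_jitter_sd SD of symmetric correlation-scale noise added per
#'   region (jitter is redrawn until the matrix stays positive definite),
#'   default 0.02.
#' @param depth_lognormal c(meanlog, sdlog) of the per-sample sequencing
#'   depth, default c(log(30000), 0.3).
#' @param n_pathways Number of pathway columns, default 40.
#' @param pathway_effects Data frame (pathway, i, j, beta1, beta2, gamma0,
#'   gamma_slope_per_grade, noise_sd) of planted pathway models
#'   \eqn{Y = \beta_1 x_1 + \beta_2 x_2 + \gamma(g) x_1 x_2 + \epsilon};
#'   unlisted pathways are pure noise.
#' @param covariate_rates Named list of Bernoulli rates for the binary
#'   covariates (female, smoking, antibiotics, diabetes, hypercholesterolemia,
#'   obesity); covariates are independent of the microbes.
#' @param latent_mean_sd SD of the per-taxon mean log abundances, default 1.2.
#' @param latent_sd Per-taxon SD of latent log abundance, default 1.
#' @param phylum_weights Named taxon-to-phylum assignment weights
#'   (Firmicutes-heavy by default, 8 phyla).
#' @param seed Integer seed, default 1.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_taxa = 60, n_regions = 14, samples_per_region = 494,
                       grade_proportions = c(4644, 1425, 581, 259) / 6909,
                       base_correlation = NULL,
                       differential_edges = NULL,
                       severity_edges = NULL,
                       region_jitter_sd = 0.02,
                       depth_lognormal = c(log(30000), 0.3),
                       n_pathways = 40,
                       pathway_effects = NULL,
                       covariate_rates = list(female = 0.55, smoking = 0.33,
                                              antibiotics = 0.10,
                                              diabetes = 0.10,
                                              hypercholesterolemia = 0.15,
                                              obesity = 0.10),
                       latent_mean_sd = 1.2, latent_sd = 1,
                       phylum_weights = c(Firmicutes = 0.58,
                                          Bacteroidetes = 0.12,
                                          Proteobacteria = 0.12,
                                          Actinobacteria = 0.08,
                                          Verrucomicrobia = 0.03,
                                          Fusobacteria = 0.03,
                                          Tenericutes = 0.02,
                                          Cyanobacteria = 0.02),
                       seed = 1) {
  if (abs(sum(grade_proportions) - 1) > 1e-12) {
    stop("grade_proportions must sum to 1 (got ", sum(grade_proportions), ")")
  }
  stopifnot(n_taxa >= 2, n_regions >= 1, samples_per_region >= 1,
            region_jitter_sd >= 0, length(depth_lognormal) == 2)
  if (is.null(base_correlation)) {
    base_correlation <- block_correlation(n_taxa, 4, 0.45)
  }
  base_correlation <- as.matrix(base_correlation)
  stopifnot(nrow(base_correlation) == n_taxa,
            isSymmetric(unname(base_correlation)))
  me <- min_eigenvalue(base_correlation)
  if (me <= 1e-6) {
    # name the offending leading principal block for the diagnostic
    bad <- NA_integer_
    for (k in 2:n_taxa) {
      if (min_eigenvalue(base_correlation[1:k, 1:k, drop = FALSE]) <= 1e-6) {
        bad <- k; break
      }
    }
    stop("base_correlation is not positive definite (min eigenvalue ",
         signif(me, 3), "); first offending leading block has size ", bad)
  }
  in_range <- function(d) d[d$i <= n_taxa & d$j <= n_taxa, , drop = FALSE]
  if (is.null(differential_edges)) {
    differential_edges <- in_range(data.frame(
      i = c(1, 9, 17, 2, 10, 3),
      j = c(6, 14, 22, 7, 15, 8),
      rho_control = c(0.10, 0.10, 0.10, 0.50, 0.50, 0.30),
      rho_case = c(0.55, 0.55, 0.55, 0.15, 0.15, -0.30),
      class = c("increased", "increased", "increased",
                "decreased", "decreased", "reversed"),
      stringsAsFactors = FALSE))
  }
  if (is.null(severity_edges)) {
    severity_edges <- in_range(data.frame(
      i = c(25, 33, 41), j = c(30, 38, 46),
      rho_slope_per_grade = c(0.15, 0.15, 0.15)))
  }
  if (is.null(pathway_effects)) {
    pathway_effects <- in_range(data.frame(
      pathway = c("PWY001", "PWY002", "PWY003", "PWY004"),
      i = c(25, 33, 41, 25), j = c(30, 38, 46, 33),
      beta1 = 0.3, beta2 = 0.3, gamma0 = 0.1,
      gamma_slope_per_grade = 0.2, noise_sd = 1,
      stringsAsFactors = FALSE))
  }
  ok_pair <- function(d) all(d$i >= 1 & d$i <= n_taxa & d$j >= 1 &
                               d$j <= n_taxa & d$i != d$j)
  stopifnot(ok_pair(differential_edges), ok_pair(severity_edges),
            ok_pair(pathway_effects))
  cfg <- list(n_taxa = n_taxa, n_regions = n_regions,
              samples_per_region = samples_per_region,
              grade_proportions = grade_proportions,
              base_correlation = base_correlation,
              differential_edges = differential_edges,
              severity_edges = severity_edges,
              region_jitter_sd = region_jitter_sd,
              depth_lognormal = depth_lognormal,
              n_pathways = n_pathways, pathway_effects = pathway_effects,
              covariate_rates = covariate_rates,
              latent_mean_sd = latent_mean_sd, latent_sd = latent_sd,
              phylum_weights = phylum_weights, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# Planted correlation matrix for one grade (before regional jitter).
grade_correlation <- function(cfg, g) {
  C <- cfg$base_correlation
  de <- cfg$differential_edges
  for (e in seq_len(nrow(de))) {
    r <- if (g == 0) de$rho_control[e] else de$rho_case[e]
    C[de$i[e], de$j[e]] <- C[de$j[e], de$i[e]] <- r
  }
  se <- cfg$severity_edges
  for (e in seq_len(nrow(se))) {
    r0 <- cfg$base_correlation[se$i[e], se$j[e]]
    r <- min(max(r0 + se$rho_slope_per_grade[e] * g, -0.9), 0.9)
    C[se$i[e], se$j[e]] <- C[se$j[e], se$i[e]] <- r
  }
  C
}

# Add symmetric off-diagonal jitter, redrawing until positive definite.
jitter_correlation <- function(C, sd) {
  if (sd == 0) return(C)
  p <- ncol(C)
  for (try in 1:100) {
    J <- matrix(0, p, p)
    J[upper.tri(J)] <- stats::rnorm(p * (p - 1) / 2, 0, sd)
    J <- J + t(J)
    Cj <- C + J
    diag(Cj) <- 1
    if (min_eigenvalue(Cj) > 1e-6) return(Cj)
  }
  stop("could not draw a positive-definite jittered correlation matrix; ",
       "reduce region_jitter_sd")
}

# SBP/DBP bands per grade; the non-driving measure stays in its grade-0 band
# so assign_grade() round-trips exactly.
draw_bp <- function(grade) {
  n <- length(grade)
  sbp <- stats::runif(n, 100, 139)
  dbp <- stats::runif(n, 60, 89)
  hi <- which(grade >= 1)
  if (length(hi) > 0) {
    driver_sbp <- stats::runif(length(hi)) < 0.5
    s_lo <- c(140, 160, 180)[grade[hi]]
    s_hi <- c(160, 180, 220)[grade[hi]]
    d_lo <- c(90, 100, 110)[grade[hi]]
    d_hi <- c(100, 110, 140)[grade[hi]]
    sbp[hi] <- ifelse(driver_sbp,
                      stats::runif(length(hi), s_lo, s_hi - 1e-6),
                      stats::runif(length(hi), 100, 139))
    dbp[hi] <- ifelse(driver_sbp,
                      stats::runif(length(hi), 60, 89),
                      stats::runif(length(hi), d_lo, d_hi - 1e-6))
  }
  list(sbp = sbp, dbp = dbp)
}

#' Simulate a region-stratified compositional cohort
#'
#' Draws, per region and hypertension grade, latent log abundances from a
#' multivariate normal with the planted (jittered) correlation structure,
#' converts them to counts via \code{Multinomial(depth, softmax(latent))} with
#' log-normal depths, assigns blood pressure uniformly within the grade's
#' band, draws the eight covariates from cohort-level distributions, and
#' builds pathway abundances from the planted interaction models. The full
#' ground truth (per-stratum correlation matrices, planted edges, pathway
#' coefficients, per-sample latent values) is returned as a manifest.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{"coabnet_cohort"}: \code{counts} (integer
#'   matrix samples x genera), \code{taxonomy} (genus, phylum),
#'   \code{metadata}, \code{pathways} (matrix samples x pathways),
#'   \code{manifest}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    p <- cfg$n_taxa
    taxa <- sprintf("g%03d", seq_len(p))
    phyla <- sample(names(cfg$phylum_weights), p, replace = TRUE,
                    prob = cfg$phylum_weights)
    taxonomy <- data.frame(genus = taxa, phylum = phyla,
                           stringsAsFactors = FALSE)
    mu <- stats::rnorm(p, 0, cfg$latent_mean_sd)
    sd_vec <- rep_len(cfg$latent_sd, p)

    # planted correlation matrices per (region, grade)
    corr <- vector("list", cfg$n_regions)
    for (r in seq_len(cfg$n_regions)) {
      corr[[r]] <- lapply(0:3, function(g)
        jitter_correlation(grade_correlation(cfg, g), cfg$region_jitter_sd))
      names(corr[[r]]) <- as.character(0:3)
    }

    n_total <- cfg$n_regions * cfg$samples_per_region
    region <- rep(sprintf("R%02d", seq_len(cfg$n_regions)),
                  each = cfg$samples_per_region)
    grade <- as.integer(sample(0:3, n_total, replace = TRUE,
                               prob = cfg$grade_proportions))
    sample_id <- sprintf("S%05d", seq_len(n_total))

    latent <- matrix(NA_real_, n_total, p,
                     dimnames = list(sample_id, taxa))
    for (r in seq_len(cfg$n_regions)) {
      for (g in 0:3) {
        idx <- which(region == sprintf("R%02d", r) & grade == g)
        if (length(idx) == 0) next
        C <- corr[[r]][[as.character(g)]]
        Sig <- C * outer(sd_vec, sd_vec)
        L <- chol(Sig)
        Z <- matrix(stats::rnorm(length(idx) * p), length(idx), p)
        latent[idx, ] <- sweep(Z %*% L, 2, mu, "+")
      }
    }

    depth <- pmax(1L, as.integer(round(
      stats::rlnorm(n_total, cfg$depth_lognormal[1], cfg$depth_lognormal[2]))))
    counts <- matrix(0L, n_total, p, dimnames = list(sample_id, taxa))
    for (i in seq_len(n_total)) {
      counts[i, ] <- as.integer(
        stats::rmultinom(1, depth[i], softmax(latent[i, ])))
    }

    bp <- draw_bp(grade)
    cr <- cfg$covariate_rates
    metadata <- data.frame(
      sample_id = sample_id, region = region,
      sbp = bp$sbp, dbp = bp$dbp, grade = grade,
      hypertension = grade >= 1, depth = depth,
      age = stats::rnorm(n_total, 53, 15),
      sex = as.integer(stats::runif(n_total) < cr$female),
      bmi = stats::rnorm(n_total, 23.4, 3.5),
      smoking = as.integer(stats::runif(n_total) < cr$smoking),
      antibiotics = as.integer(stats::runif(n_total) < cr$antibiotics),
      diabetes = as.integer(stats::runif(n_total) < cr$diabetes),
      hypercholesterolemia =
        as.integer(stats::runif(n_total) < cr$hypercholesterolemia),
      obesity = as.integer(stats::runif(n_total) < cr$obesity),
      stringsAsFactors = FALSE)

    pw_names <- sprintf("PWY%03d", seq_len(cfg$n_pathways))
    pathways <- matrix(stats::rnorm(n_total * cfg$n_pathways), n_total,
                       cfg$n_pathways, dimnames = list(sample_id, pw_names))
    pe <- cfg$pathway_effects
    for (e in seq_len(nrow(pe))) {
      pw <- as.character(pe$pathway[e])
      if (!pw %in% pw_names) pathways <- cbind(pathways,
        matrix(0, n_total, 1, dimnames = list(NULL, pw)))
      x1 <- latent[, pe$i[e]] - mu[pe$i[e]]
      x2 <- latent[, pe$j[e]] - mu[pe$j[e]]
      gam <- pe$gamma0[e] + pe$gamma_slope_per_grade[e] * grade
      pathways[, pw] <- pe$beta1[e] * x1 + pe$beta2[e] * x2 +
        gam * x1 * x2 + stats::rnorm(n_total, 0, pe$noise_sd[e])
    }

    manifest <- list(
      config_seed = cfg$seed,
      correlations = stats::setNames(corr,
                                     sprintf("R%02d", seq_len(cfg$n_regions))),
      differential_edges = cfg$differential_edges,
      severity_edges = cfg$severity_edges,
      pathway_effects = cfg$pathway_effects,
      taxa = taxa, mu = mu, latent_sd = sd_vec,
      latent = latent)

    structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata,
                   pathways = pathways, manifest = manifest),
              class = "coabnet_cohort")
  })
}

#' @export
print.coabnet_cohort <- function(x, ...) {
  cat("Synthetic microbiome cohort\n")
  cat(sprintf("  %d samples x %d genera, %d regions, %d pathways\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$region)), ncol(x$pathways)))
  tab <- table(x$metadata$grade)
  cat("  grade counts:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
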