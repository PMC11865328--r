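#' Per-grade pooled co-abundance networks
#'
#' For each hypertension grade, fits the latent-correlation estimator per
#' region stratum (strata below the sample-size floor are dropped with a
#' message) and pools the strata by random-effects meta-analysis, exactly as
#' for the condition-level networks. When a grade has no region stratum at or
#' above the floor, the \code{"combined"} fallback fits one network on all of
#' the grade's samples pooled across regions (grades 2-3 are typically too
#' small per region for stratified fits).
#'
#' @param counts Count matrix (samples x genera), rarefied and filtered.
#' @param metadata Data frame with sample_id, region and grade columns, rows
#'   matching \code{rownames(counts)}.
#' @param lambda Penalty for \code{\link{cclasso}}.
#' @param grades Grades to fit, default 0:3.
#' @param min_stratum_n Stratum floor, default 20.
#' @param mode \code{"stratified"} (per-region fits then pooling; combined
#'   fallback per grade when no stratum passes the floor) or \code{"combined"}
#'   (one fit per grade on all samples).
#' @param ... Passed to \code{\link{cclasso}}.
#' @return Named list (one element per grade, names "0".."3") of pooled edge
#'   data frames as returned by \code{\link{meta_network}}.
#' @export
grade_networks <- function(counts, metadata, lambda = 0.05, grades = 0:3,
                           min_stratum_n = 20,
                           mode = c("stratified", "combined"), ...) {
  mode <- match.arg(mode)
  stopifnot(nrow(counts) == nrow(metadata))
  out <- list()
  for (g in grades) {
    in_grade <- metadata$grade == g
    strata <- list()
    if (mode == "stratified") {
      for (r in unique(metadata$region[in_grade])) {
        idx <- which(in_grade & metadata$region == r)
        if (length(idx) >= min_stratum_n) {
          strata[[as.character(r)]] <-
            stratum_edges(counts[idx, , drop = FALSE], lambda = lambda, ...)
        }
      }
      if (length(strata) == 0 && sum(in_grade) >= min_stratum_n) {
        message("grade ", g, ": no region stratum with n >= ", min_stratum_n,
                "; falling back to a combined fit")
      }
    }
    if (length(strata) == 0) {
      if (sum(in_grade) < min_stratum_n) {
        stop("grade ", g, " has no usable stratum (n = ", sum(in_grade), ")")
      }
      strata[["combined"]] <-
        stratum_edges(counts[in_grade, , drop = FALSE], lambda = lambda, ...)
    }
    out[[as.character(g)]] <- meta_network(strata)
  }
  out
}

#' Trend of edge strength with hypertension grade
#'
#' Weighted least squares of pooled Fisher-z edge strength on the numeric
#' grade index (0-3) with weights 1/se^2; the slope's t-test p-value is
#' reported. Requires at least three estimable grades.
#'
#' @param z Pooled Fisher-z effects per grade.
#' @param se Their standard errors.
#' @param grades Numeric grade scores, default \code{seq_along(z) - 1}.
#' @param weighted Use 1/se^2 weights (default); otherwise ordinary least
#'   squares.
#' @return List with slope, se, p, n_grades; all NA (with a warning) when
#'   fewer than three grades are estimable.
#' @export
severity_trend <- function(z, se, grades = seq_along(z) - 1, weighted = TRUE) {
  ok <- is.finite(z) & is.finite(se) & se > 0
  if (sum(ok) < 3) {
    warning("fewer than 3 estimable grades; severity trend undefined")
    return(list(slope = NA_real_, se = NA_real_, p = NA_real_,
                n_grades = sum(ok)))
  }
  d <- data.frame(z = z[ok], g = grades[ok])
  w <- if (weighted) 1 / se[ok]^2 else rep(1, sum(ok))
  fit <- stats::lm(z ~ g, data = d, weights = w)
  cf <- summary(fit)$coefficients
  list(slope = cf["g", "Estimate"], se = cf["g", "Std. Error"],
       p = cf["g", "Pr(>|t|)"], n_grades = sum(ok))
}

#' Severity-related edges: heterogeneity across grades plus trend
#'
#' Implements the funnel applied to condition-differential edges: for each
#' candidate edge, Cochran's Q across the per-grade pooled effects (default
#' thresholds I-squared > 75, p < 0.05), then, for heterogeneous edges, the
#' weighted linear trend of strength on grade (significant at
#' \code{trend_p_threshold}).
#'
#' @param candidate_edges Data frame with genus_i, genus_j: the edges to test
#'   (e.g. the heterogeneous rows of \code{\link{differential_network}}).
#' @param grade_metas Named list of per-grade pooled networks from
#'   \code{\link{grade_networks}}.
#' @param i2_threshold,p_threshold Grade-heterogeneity thresholds.
#' @param trend_p_threshold Trend significance threshold, default 0.05.
#' @return Data frame with per-grade z/se columns, Q, I2, p_het,
#'   grade_heterogeneous, slope, trend_se, trend_p, severity_associated.
#' @export
severity_edges <- function(candidate_edges, grade_metas, i2_threshold = 75,
                           p_threshold = 0.05, trend_p_threshold = 0.05) {
  grades <- as.numeric(names(grade_metas))
  keys <- lapply(grade_metas, function(m) edge_key(m$genus_i, m$genus_j))
  ck <- edge_key(candidate_edges$genus_i, candidate_edges$genus_j)
  rows <- lapply(seq_along(ck), function(e) {
    z <- se <- rep(NA_real_, length(grades))
    for (gi in seq_along(grades)) {
      m <- match(ck[e], keys[[gi]])
      if (!is.na(m)) {
        z[gi] <- grade_metas[[gi]]$pooled_z[m]
        se[gi] <- grade_metas[[gi]]$se[m]
      }
    }
    ok <- is.finite(z) & is.finite(se)
    het <- if (sum(ok) >= 2) cochran_q_between(z[ok], se[ok]) else
      list(Q = NA_real_, df = NA, p = NA_real_, I2 = NA_real_)
    row <- data.frame(genus_i = candidate_edges$genus_i[e],
                      genus_j = candidate_edges$genus_j[e],
                      stringsAsFactors = FALSE)
    for (gi in seq_along(grades)) {
      row[[paste0("z_g", grades[gi])]] <- z[gi]
      row[[paste0("se_g", grades[gi])]] <- se[gi]
    }
    row$Q <- het$Q; row$I2 <- het$I2; row$p_het <- het$p
    row
  })
  out <- do.call(rbind, rows)
  out$grade_heterogeneous <- !is.na(out$p_het) &
    out$I2 > i2_threshold & out$p_het < p_threshold
  out$slope <- out$trend_se <- out$trend_p <- NA_real_
  zc <- paste0("z_g", grades); sc <- paste0("se_g", grades)
  for (e in which(out$grade_heterogeneous)) {
    tr <- suppressWarnings(
      severity_trend(as.numeric(out[e, zc]), as.numeric(out[e, sc]), grades))
    out$slope[e] <- tr$slope; out$trend_se[e] <- tr$se; out$trend_p[e] <- tr$p
  }
  out$severity_associated <- !is.na(out$trend_p) &
    out$trend_p < trend_p_threshold
  rownames(out) <- NULL
  out
}

#' Differential abundance of genera or pathways
#'
#' Each feature is inverse-rank transformed and residualized on the covariates,
#' then tested: \code{two_group} compares hypertensive vs non-hypertensive
#' residuals with a Wilcoxon rank-sum test; \code{four_grade} runs a
#' Kruskal-Wallis test across the grades plus a Spearman trend of residuals on
#' the numeric grade. BH FDR is applied within the call (one feature family per
#' call: test genera and pathways separately).
#'
#' @param features Matrix (samples x features) of abundances (counts or
#'   relative values).
#' @param metadata Data frame with \code{hypertension} (logical) and
#'   \code{grade} columns plus the covariate columns.
#' @param mode \code{"two_group"} or \code{"four_grade"}.
#' @param covariate_cols Covariate column names in \code{metadata}; default
#'   the eight standard confounders.
#' @return Data frame with feature, statistic, p, q and (four_grade mode)
#'   spearman_rho, spearman_p, spearman_q and per-grade medians.
#' @export
differential_abundance <- function(features, metadata,
                                   mode = c("two_group", "four_grade"),
                                   covariate_cols = c("age", "sex", "bmi",
                                     "smoking", "antibiotics", "diabetes",
                                     "hypercholesterolemia", "obesity")) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(metadata),
            all(covariate_cols %in% names(metadata)))
  X <- as.matrix(metadata[, covariate_cols])
  grade <- metadata$grade
  hyp <- if ("hypertension" %in% names(metadata)) metadata$hypertension else
    grade >= 1
  res <- matrix(NA_real_, nrow(features), ncol(features),
                dimnames = dimnames(features))
  constant <- logical(ncol(features))
  for (j in seq_len(ncol(features))) {
    v <- features[, j]
    if (max(v) == min(v)) {
      constant[j] <- TRUE
      res[, j] <- 0
    } else {
      res[, j] <- residualize(inverse_rank_transform(v), X)
    }
  }
  out <- data.frame(feature = colnames(features) %||%
                      paste0("f", seq_len(ncol(features))),
                    constant = constant, stringsAsFactors = FALSE)
  if (mode == "two_group") {
    tests <- lapply(seq_len(ncol(features)), function(j) {
      if (constant[j]) return(c(NA_real_, 1))
      t <- stats::wilcox.test(res[hyp, j], res[!hyp, j], exact = FALSE)
      c(unname(t$statistic), t$p.value)
    })
    tests <- do.call(rbind, tests)
    out$statistic <- tests[, 1]
    out$p <- tests[, 2]
  } else {
    tests <- lapply(seq_len(ncol(features)), function(j) {
      if (constant[j]) return(c(NA_real_, 1, NA_real_, 1))
      kw <- stats::kruskal.test(res[, j], factor(grade))
      sp <- suppressWarnings(
        stats::cor.test(res[, j], grade, method = "spearman", exact = FALSE))
      c(unname(kw$statistic), kw$p.value, unname(sp$estimate), sp$p.value)
    })
    tests <- do.call(rbind, tests)
    out$statistic <- tests[, 1]
    out$p <- tests[, 2]
    out$spearman_rho <- tests[, 3]
    out$spearman_p <- tests[, 4]
    for (g in sort(unique(grade))) {
      out[[paste0("median_g", g)]] <-
        apply(res[grade == g, , drop = FALSE], 2, stats::median)
    }
  }
  out$q <- bh_fdr(out$p)
  if (mode == "four_grade") out$spearman_q <- bh_fdr(out$spearman_p)
  out
}
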