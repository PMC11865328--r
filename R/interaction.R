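#' Extra variance from a genus-pair interaction term
#'
#' Fits the nested pair of linear models
#' \deqn{Y = \alpha + \beta_1 x_1 + \beta_2 x_2 + \epsilon}
#' \deqn{Y = \alpha + \beta_1 x_1 + \beta_2 x_2 + \beta_{12} x_1 x_2 + \epsilon}
#' and reports the extra variance explained by the interaction,
#' \eqn{\Delta R^2 = R^2_{full} - R^2_{reduced}}, with the partial F statistic
#' \eqn{F = \Delta R^2 (n - 4) / (1 - R^2_{full})} on (1, n - 4) degrees of
#' freedom. Inputs are expected to be transformed/residualized abundances.
#'
#' @param y Pathway abundance (transformed), length n >= 10.
#' @param x1,x2 Genus abundances (transformed), same length.
#' @return One-row data frame: n, alpha, beta1, beta2, beta12, sigma2,
#'   r2_reduced, r2_full, delta_r2, F, p, skipped. Near-collinear genera
#'   (|cor| > 0.999) are flagged \code{skipped = TRUE} with NA statistics.
#' @export
fit_interaction <- function(y, x1, x2) {
  n <- length(y)
  stopifnot(length(x1) == n, length(x2) == n)
  if (n < 10) stop("at least 10 observations are required (n = ", n, ")")
  empty <- data.frame(n = n, alpha = NA_real_, beta1 = NA_real_,
                      beta2 = NA_real_, beta12 = NA_real_, sigma2 = NA_real_,
                      r2_reduced = NA_real_, r2_full = NA_real_,
                      delta_r2 = NA_real_, F = NA_real_, p = NA_real_,
                      skipped = TRUE)
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0 ||
      abs(stats::cor(x1, x2)) > 0.999) {
    warning("collinear or constant genus pair; interaction fit skipped")
    return(empty)
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(empty)
  red <- stats::lm(y ~ x1 + x2)
  full <- stats::lm(y ~ x1 + x2 + I(x1 * x2))
  r2r <- 1 - sum(red$residuals^2) / tss
  r2f <- 1 - sum(full$residuals^2) / tss
  dr2 <- max(r2f - r2r, 0)
  Fst <- if (r2f < 1) dr2 * (n - 4) / (1 - r2f) else Inf
  cf <- stats::coef(full)
  data.frame(n = n, alpha = unname(cf[1]), beta1 = unname(cf[2]),
             beta2 = unname(cf[3]), beta12 = unname(cf[4]),
             sigma2 = sum(full$residuals^2) / (n - 4),
             r2_reduced = r2r, r2_full = r2f, delta_r2 = dr2, F = Fst,
             p = stats::pf(Fst, 1, n - 4, lower.tail = FALSE),
             skipped = FALSE)
}

#' Trend of interaction extra variance across grades
#'
#' Ordinary least squares of per-grade \eqn{\Delta R^2} on the numeric grade
#' index, with the slope's t-test p-value. Needs at least three grades with a
#' valid fit.
#'
#' @param delta_r2 Extra variance per grade.
#' @param grades Numeric grade scores, default \code{seq_along(delta_r2) - 1}.
#' @return List with slope, se, p, n_grades (NAs with a warning when fewer
#'   than three grades are valid).
#' @export
variance_trend <- function(delta_r2, grades = seq_along(delta_r2) - 1) {
  ok <- is.finite(delta_r2)
  if (sum(ok) < 3) {
    warning("fewer than 3 grades with valid interaction fits; trend undefined")
    return(list(slope = NA_real_, se = NA_real_, p = NA_real_,
                n_grades = sum(ok)))
  }
  fit <- stats::lm(delta_r2[ok] ~ grades[ok])
  cf <- summary(fit)$coefficients
  list(slope = cf[2, "Estimate"], se = cf[2, "Std. Error"],
       p = cf[2, "Pr(>|t|)"], n_grades = sum(ok))
}

#' Funnel of severity-related pathways
#'
#' Returns the pathways passing, in order: two-group differential abundance
#' (q < threshold), four-grade Kruskal-Wallis (q < threshold), and the Spearman
#' trend with grade (q < threshold) — the candidate set fed to the interaction
#' models.
#'
#' @param da_two_group Output of \code{\link{differential_abundance}} in
#'   two_group mode on the pathway table.
#' @param da_four_grade Output in four_grade mode on the same table.
#' @param q_threshold FDR threshold at each step, default 0.05.
#' @return Character vector of pathway names.
#' @export
pathway_screen <- function(da_two_group, da_four_grade, q_threshold = 0.05) {
  if (nrow(da_two_group) == 0) return(character())
  step1 <- da_two_group$feature[!is.na(da_two_group$q) &
                                  da_two_group$q < q_threshold]
  i4 <- match(step1, da_four_grade$feature)
  step2 <- step1[!is.na(i4) & da_four_grade$q[i4] < q_threshold]
  i4 <- match(step2, da_four_grade$feature)
  step2[da_four_grade$spearman_q[i4] < q_threshold]
}

#' Interaction-variance scan across pathways, genus pairs and grades
#'
#' For every combination of screened pathway, candidate genus pair and grade,
#' fits \code{\link{fit_interaction}} within the grade stratum, applies BH FDR
#' jointly across all F-tests, and fits the per-combination
#' \code{\link{variance_trend}} of extra variance on grade.
#'
#' @param pathway_res Matrix (samples x pathways) of transformed, residualized
#'   pathway abundances.
#' @param genus_res Matrix (samples x genera) of transformed, residualized
#'   genus abundances.
#' @param pairs Data frame with genus_i, genus_j.
#' @param grade Per-sample grade vector.
#' @param pathways Pathway names to scan (default all columns).
#' @param grades Grade values, default 0:3.
#' @param min_n Minimum stratum size for a fit, default 10.
#' @return List with \code{fits} (one row per pathway x pair x grade, with q)
#'   and \code{trends} (one row per pathway x pair: slope, p_trend, n_grades).
#' @export
interaction_scan <- function(pathway_res, genus_res, pairs, grade,
                             pathways = colnames(pathway_res), grades = 0:3,
                             min_n = 10) {
  stopifnot(nrow(pathway_res) == nrow(genus_res),
            nrow(pathway_res) == length(grade))
  fits <- list()
  for (pw in pathways) {
    for (e in seq_len(nrow(pairs))) {
      gi <- pairs$genus_i[e]; gj <- pairs$genus_j[e]
      if (!gi %in% colnames(genus_res) || !gj %in% colnames(genus_res)) next
      for (g in grades) {
        idx <- which(grade == g)
        if (length(idx) < min_n) next
        f <- suppressWarnings(
          fit_interaction(pathway_res[idx, pw],
                          genus_res[idx, gi], genus_res[idx, gj]))
        f <- cbind(data.frame(pathway = pw, genus_i = gi, genus_j = gj,
                              grade = g, stringsAsFactors = FALSE), f)
        fits[[length(fits) + 1L]] <- f
      }
    }
  }
  if (length(fits) == 0) {
    return(list(fits = NULL, trends = NULL))
  }
  fits <- do.call(rbind, fits)
  fits$q <- bh_fdr(ifelse(is.na(fits$p), 1, fits$p))
  key <- paste(fits$pathway, fits$genus_i, fits$genus_j, sep = "\r")
  trends <- lapply(split(seq_len(nrow(fits)), key), function(ix) {
    d <- fits[ix, , drop = FALSE]
    tr <- suppressWarnings(variance_trend(d$delta_r2, d$grade))
    data.frame(pathway = d$pathway[1], genus_i = d$genus_i[1],
               genus_j = d$genus_j[1], slope = tr$slope, p_trend = tr$p,
               n_grades = tr$n_grades, stringsAsFactors = FALSE)
  })
  trends <- do.call(rbind, trends)
  rownames(fits) <- rownames(trends) <- NULL
  list(fits = fits, trends = trends)
}
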