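#' Cochran's Q heterogeneity across effect estimates
#'
#' Fixed-effect heterogeneity test: with weights \eqn{w = 1/se^2} and weighted
#' mean \eqn{\bar\theta}, \eqn{Q = \sum w (\theta - \bar\theta)^2} is referred
#' to a chi-squared distribution with K - 1 degrees of freedom;
#' \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100} quantifies the share of
#' variability attributable to heterogeneity.
#'
#' @param effects Effect estimates (K >= 2), e.g. pooled Fisher-z values of an
#'   edge under two conditions.
#' @param ses Standard errors, same length, positive.
#' @return List with Q, df, p, I2.
#' @export
cochran_q_between <- function(effects, ses) {
  K <- length(effects)
  if (K < 2) stop("at least two effects are required for a heterogeneity test")
  stopifnot(length(ses) == K, all(ses > 0), all(is.finite(effects)))
  w <- 1 / ses^2
  m <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - m)^2)
  df <- K - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0)
}

#' Classify a differential edge
#'
#' Direction-of-change taxonomy for an edge that passed the heterogeneity
#' thresholds: \code{reversed} if the pooled effects have opposite signs,
#' otherwise \code{increased} when |z_case| > |z_control| and \code{decreased}
#' otherwise. Vectorized.
#'
#' @param z_case,z_control Pooled Fisher-z effects per condition.
#' @param sig_case,sig_control Logical significance flags per condition
#'   (carried through for sub-tallies; not used in the classification itself).
#' @return Character vector in {increased, decreased, reversed}.
#' @export
classify_differential <- function(z_case, z_control,
                                  sig_case = NULL, sig_control = NULL) {
  reversed <- sign(z_case) != sign(z_control) & z_case != 0 & z_control != 0
  ifelse(reversed, "reversed",
         ifelse(abs(z_case) > abs(z_control), "increased", "decreased"))
}

#' Differential co-abundance network between two conditions
#'
#' For every edge in the union of the two conditions' significant networks,
#' tests whether the pooled edge strengths are heterogeneous between conditions
#' (Cochran's Q on the two pooled Fisher-z effects with their pooled SEs) and
#' classifies edges passing both thresholds (default I-squared > 75 and
#' p < 0.05) as increased / decreased / reversed in the case condition.
#'
#' @param meta_case,meta_control Pooled networks from \code{\link{meta_network}}
#'   for the case (e.g. hypertensive) and control condition.
#' @param i2_threshold I-squared threshold in percent, default 75.
#' @param p_threshold Heterogeneity p-value threshold, default 0.05.
#' @param universe \code{"union_significant"} (default: edges significant in
#'   either condition) or \code{"all"} (every edge pooled in both).
#' @return Data frame with per-edge z/se per condition, Q, I2, p_het,
#'   heterogeneous flag, class (NA where not heterogeneous), and the
#'   per-condition significance flags.
#' @export
differential_network <- function(meta_case, meta_control, i2_threshold = 75,
                                 p_threshold = 0.05,
                                 universe = c("union_significant", "all")) {
  universe <- match.arg(universe)
  kc <- edge_key(meta_case$genus_i, meta_case$genus_j)
  kn <- edge_key(meta_control$genus_i, meta_control$genus_j)
  shared <- intersect(kc, kn)
  ic <- match(shared, kc)
  in_ <- match(shared, kn)
  keep <- if (universe == "union_significant") {
    meta_case$significant[ic] | meta_control$significant[in_]
  } else rep(TRUE, length(shared))
  ic <- ic[keep]; in_ <- in_[keep]
  if (length(ic) == 0) {
    warning("no edges in the differential test universe")
  }
  het <- mapply(function(zc, sc, zn, sn) {
    h <- cochran_q_between(c(zc, zn), c(sc, sn))
    c(h$Q, h$p, h$I2)
  }, meta_case$pooled_z[ic], meta_case$se[ic],
     meta_control$pooled_z[in_], meta_control$se[in_])
  het <- matrix(het, nrow = 3)
  out <- data.frame(
    genus_i = meta_case$genus_i[ic], genus_j = meta_case$genus_j[ic],
    z_case = meta_case$pooled_z[ic], se_case = meta_case$se[ic],
    z_control = meta_control$pooled_z[in_], se_control = meta_control$se[in_],
    Q = het[1, ], p_het = het[2, ], I2 = het[3, ],
    sig_case = meta_case$significant[ic],
    sig_control = meta_control$significant[in_],
    stringsAsFactors = FALSE)
  out$heterogeneous <- out$I2 > i2_threshold & out$p_het < p_threshold
  out$class <- NA_character_
  if (any(out$heterogeneous)) {
    h <- out$heterogeneous
    out$class[h] <- classify_differential(out$z_case[h], out$z_control[h])
  }
  rownames(out) <- NULL
  out
}

#' Partial correlation matrix from a correlation matrix
#'
#' Inverts the correlation matrix to the precision matrix \eqn{\Omega} and
#' returns \eqn{-\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}}: the correlation
#' of each pair after removing the linear effects of all other variables. A
#' singular input is lifted by a 1e-8 ridge on the diagonal (with a message).
#'
#' @param R Symmetric correlation (or covariance) matrix.
#' @return Matrix of partial correlations with unit diagonal.
#' @export
partial_correlation <- function(R) {
  R <- as.matrix(R)
  stopifnot(isSymmetric(unname(R)))
  omega <- tryCatch(solve(R), error = function(e) {
    message("singular correlation matrix; adding ridge 1e-8 to the diagonal")
    solve(R + diag(1e-8, ncol(R)))
  })
  d <- diag(omega)
  P <- -omega / sqrt(outer(d, d))
  diag(P) <- 1
  dimnames(P) <- dimnames(R)
  P
}

#' Covariate-adjusted edge estimates by partial correlation
#'
#' Per stratum and per edge, builds the Pearson correlation matrix of the two
#' genera (transformed abundances) together with the covariates, and takes the
#' genus-genus partial correlation from its inverse as the adjusted edge
#' correlation. The adjusted per-stratum estimates can be re-pooled with
#' \code{\link{meta_network}} and compared to the unadjusted pooled effects
#' with \code{\link{edge_consistency}}.
#'
#' @param edges Data frame of edges (columns genus_i, genus_j) to adjust.
#' @param abundances_by_stratum Named list of per-stratum matrices of
#'   transformed abundances (samples x genera, columns named by genus).
#' @param covariates_by_stratum Named list (same names) of per-stratum
#'   covariate matrices, rows aligned with the abundance rows.
#' @return Named list of per-stratum data frames (genus_i, genus_j, r, n)
#'   holding the adjusted correlations.
#' @export
adjust_partial_correlation <- function(edges, abundances_by_stratum,
                                       covariates_by_stratum) {
  stopifnot(identical(names(abundances_by_stratum),
                      names(covariates_by_stratum)))
  lapply(stats::setNames(names(abundances_by_stratum),
                         names(abundances_by_stratum)), function(s) {
    ab <- abundances_by_stratum[[s]]
    cv <- as.matrix(covariates_by_stratum[[s]])
    stopifnot(nrow(ab) == nrow(cv))
    r_adj <- vapply(seq_len(nrow(edges)), function(e) {
      gi <- edges$genus_i[e]; gj <- edges$genus_j[e]
      if (!gi %in% colnames(ab) || !gj %in% colnames(ab)) return(NA_real_)
      R <- stats::cor(cbind(ab[, gi], ab[, gj], cv))
      partial_correlation(R)[1, 2]
    }, numeric(1))
    data.frame(genus_i = edges$genus_i, genus_j = edges$genus_j,
               r = r_adj, n = nrow(ab), stringsAsFactors = FALSE)
  })
}

#' Per-edge consistency between two pooled networks
#'
#' Cochran's Q test between the pooled effects of each edge shared by two
#' pooled networks (e.g. unadjusted vs covariate-adjusted, or primary vs
#' replication); an edge is consistent when the heterogeneity p exceeds
#' \code{p_threshold}.
#'
#' @param meta_a,meta_b Pooled networks from \code{\link{meta_network}}.
#' @param p_threshold Consistency threshold, default 0.05.
#' @return Data frame with genus_i, genus_j, z_a, z_b, Q, p_het, consistent.
#' @export
edge_consistency <- function(meta_a, meta_b, p_threshold = 0.05) {
  ka <- edge_key(meta_a$genus_i, meta_a$genus_j)
  kb <- edge_key(meta_b$genus_i, meta_b$genus_j)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  if (length(shared) == 0) {
    warning("no shared edges between the two networks")
    return(data.frame(genus_i = character(), genus_j = character(),
                      z_a = numeric(), z_b = numeric(), Q = numeric(),
                      p_het = numeric(), consistent = logical()))
  }
  het <- mapply(function(za, sa, zb, sb) {
    h <- cochran_q_between(c(za, zb), c(sa, sb))
    c(h$Q, h$p)
  }, meta_a$pooled_z[ia], meta_a$se[ia], meta_b$pooled_z[ib], meta_b$se[ib])
  het <- matrix(het, nrow = 2)
  data.frame(genus_i = meta_a$genus_i[ia], genus_j = meta_a$genus_j[ia],
             z_a = meta_a$pooled_z[ia], z_b = meta_b$pooled_z[ib],
             Q = het[1, ], p_het = het[2, ],
             consistent = het[2, ] > p_threshold,
             stringsAsFactors = FALSE)
}

#' Replication of a pooled network in independent cohorts
#'
#' Pools the replication cohorts' per-cohort edge estimates into one
#' replication effect per edge (same random-effects machinery), then, for each
#' primary-significant edge estimable in the replication set, reports whether
#' it replicates (replication p < 0.05 with the same sign) and whether its
#' strength is consistent with the primary estimate (Cochran's Q p > 0.05).
#'
#' @param primary_meta Pooled primary network (\code{\link{meta_network}}).
#' @param replication_strata Named list of per-cohort edge data frames
#'   (genus_i, genus_j, r, n).
#' @param sig_p Replication significance threshold, default 0.05.
#' @return List with the per-edge table and tallies: n_evaluable,
#'   n_replicated, pct_replicated, n_consistent, pct_consistent.
#' @export
compare_replication <- function(primary_meta, replication_strata,
                                sig_p = 0.05) {
  rep_meta <- meta_network(replication_strata, k_min = 1)
  prim_sig <- primary_meta[primary_meta$significant, , drop = FALSE]
  kp <- edge_key(prim_sig$genus_i, prim_sig$genus_j)
  kr <- edge_key(rep_meta$genus_i, rep_meta$genus_j)
  shared <- intersect(kp, kr)
  if (length(shared) == 0) {
    warning("no overlapping edges between primary and replication networks")
    return(list(table = NULL, n_evaluable = 0L, n_replicated = 0L,
                pct_replicated = NA_real_, n_consistent = 0L,
                pct_consistent = NA_real_))
  }
  ip <- match(shared, kp); ir <- match(shared, kr)
  cons <- edge_consistency(prim_sig[ip, , drop = FALSE],
                           rep_meta[ir, , drop = FALSE])
  tab <- data.frame(
    genus_i = prim_sig$genus_i[ip], genus_j = prim_sig$genus_j[ip],
    z_primary = prim_sig$pooled_z[ip], z_replication = rep_meta$pooled_z[ir],
    p_replication = rep_meta$p[ir],
    replicated = rep_meta$p[ir] < sig_p &
      sign(rep_meta$pooled_z[ir]) == sign(prim_sig$pooled_z[ip]),
    Q = cons$Q, p_het = cons$p_het, consistent = cons$consistent,
    stringsAsFactors = FALSE)
  list(table = tab,
       n_evaluable = nrow(tab),
       n_replicated = sum(tab$replicated),
       pct_replicated = 100 * mean(tab$replicated),
       n_consistent = sum(tab$consistent),
       pct_consistent = 100 * mean(tab$consistent))
}
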