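#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's reads uniformly without replacement to exactly
#' \code{depth} reads (the standard rarefaction used to equalize sequencing
#' effort across samples; 10,000 reads is the conventional depth for
#' genus-level 16S profiles). Samples with fewer than \code{depth} total reads
#' are dropped and reported via a message.
#'
#' @param counts Integer matrix, samples in rows, genera in columns, with row
#'   and column names.
#' @param depth Target depth (reads per sample), default 10000.
#' @param seed Optional integer seed; the caller's RNG stream is preserved.
#' @return The rarefied count matrix (every row sums to \code{depth}), with the
#'   IDs of dropped samples in attribute \code{"dropped"}.
#' @export
rarefy <- function(counts, depth = 10000, seed = NULL) {
  counts <- as.matrix(counts)
  stopifnot(depth > 0, all(counts >= 0))
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) {
    stop("all samples have fewer than ", depth, " reads; nothing to rarefy")
  }
  dropped <- rownames(counts)[!keep]
  if (length(dropped) > 0) {
    message(length(dropped), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  kept <- counts[keep, , drop = FALSE]
  out <- with_seed(seed, {
    exact <- rowSums(kept) == depth
    res <- kept
    if (any(!exact)) {
      # rrarefy's "should be used for observed counts" advisory fires on
      # legitimate high-count tables; everything else propagates
      res[!exact, ] <- withCallingHandlers(
        vegan::rrarefy(kept[!exact, , drop = FALSE], depth),
        warning = function(w) {
          if (grepl("observed counts", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    }
    res
  })
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- dropped
  out
}

#' Filter genera by prevalence
#'
#' Keeps genera detected (nonzero count) in at least
#' \code{ceiling(min_prevalence * n_samples)} samples; the boundary is
#' inclusive. Column order is preserved.
#'
#' @param counts Count matrix, samples in rows.
#' @param min_prevalence Fraction in (0, 1]; default 0.10.
#' @return The filtered count matrix.
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.10) {
  counts <- as.matrix(counts)
  stopifnot(min_prevalence > 0, min_prevalence <= 1)
  need <- ceiling(min_prevalence * nrow(counts))
  present <- colSums(counts > 0)
  counts[, present >= need, drop = FALSE]
}

#' Assign hypertension grade from blood pressure
#'
#' Clinical grading: grade 1 for SBP in [140, 160) or DBP in [90, 100),
#' grade 2 for SBP in [160, 180) or DBP in [100, 110), grade 3 for
#' SBP >= 180 or DBP >= 110, grade 0 otherwise. When systolic and diastolic
#' pressure imply different grades the maximum applies (the clinical
#' convention).
#'
#' @param sbp,dbp Systolic / diastolic blood pressure in mmHg (positive,
#'   vectorized).
#' @return Integer vector of grades in 0..3.
#' @export
assign_grade <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) ||
      any(sbp <= 0) || any(dbp <= 0)) {
    stop("sbp and dbp must be positive finite values (mmHg)")
  }
  gs <- findInterval(sbp, c(140, 160, 180))
  gd <- findInterval(dbp, c(90, 100, 110))
  as.integer(pmax(gs, gd))
}

#' Inverse-rank (rank-based inverse normal) transformation
#'
#' Maps values to normal quantiles \eqn{\Phi^{-1}((rank - offset)/n)} with
#' average ranks for ties. The default offset 0.5 gives a symmetric,
#' approximately mean-zero output.
#'
#' @param x Numeric vector, length >= 2.
#' @param offset Rank offset; 0.5 by default (Blom's 3/8 is another common
#'   choice).
#' @return Transformed numeric vector. A constant input returns all zeros with
#'   a warning.
#' @export
inverse_rank_transform <- function(x, offset = 0.5) {
  stopifnot(length(x) >= 2, all(is.finite(x)))
  if (max(x) == min(x)) {
    warning("constant vector: inverse-rank transform returns zeros")
    return(rep(0, length(x)))
  }
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - offset) / length(x))
}

#' Residualize a response on covariates
#'
#' Ordinary-least-squares residuals of \code{values} on an intercept plus the
#' covariate columns. Collinear covariate columns are dropped with a warning
#' (pivoted QR rank detection), so the fit is always full rank.
#'
#' @param values Numeric response vector.
#' @param covariates Numeric matrix or data.frame with one row per element of
#'   \code{values}.
#' @return Residual vector, orthogonal to the intercept and every retained
#'   covariate.
#' @export
residualize <- function(values, covariates) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  stopifnot(length(values) == nrow(covariates))
  X <- cbind(`(Intercept)` = 1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning("dropping collinear covariate column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  as.vector(qr.resid(qrX, values))
}
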