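#' Covariance of log compositions
#'
#' Converts counts to compositions with a pseudocount and returns the sample
#' covariance matrix of \code{log((count + pc) / (depth + p * pc))} across
#' samples, the input statistic of the latent-correlation estimator.
#'
#' @param counts Count matrix, samples in rows, genera in columns (rarefied or
#'   not; the per-row total is used as the depth).
#' @param pseudocount Positive pseudocount added to every cell, default 0.5.
#' @return Sample covariance matrix of the log compositions (genera x genera).
#' @export
log_composition_covariance <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(pseudocount > 0)
  if (nrow(counts) < 2) {
    stop("at least two samples are required to form a covariance matrix")
  }
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("genus with all-zero counts present (apply prevalence_filter first): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  depth <- rowSums(counts)
  lc <- log(counts + pseudocount) - log(depth + ncol(counts) * pseudocount)
  stats::cov(lc)
}

#' Latent correlation network for compositional data
#'
#' Fits the CCLasso-type estimator: given the sample covariance \eqn{S} of log
#' compositions, finds the latent (absolute-abundance scale) covariance
#' \eqn{\Sigma} and nuisance vector \eqn{b} absorbing the compositional closure
#' term by minimizing
#' \deqn{\tfrac12 \| S - \Sigma + b 1^T + 1 b^T \|_F^2 +
#'       \lambda \sum_{i<j} |\Sigma_{ij}|}
#' subject to \eqn{\Sigma \succeq 0}. The problem is solved by block coordinate
#' descent: a closed-form update of \eqn{b}, alternated with an ADMM solve of
#' the \eqn{\Sigma} block that splits the L1 proximal step (soft-thresholding
#' of off-diagonals) from projection onto the PSD cone (eigenvalue clipping).
#' The exact block minimizations make the objective non-increasing across
#' outer iterations.
#'
#' @param x Either a count matrix (samples x genera; the log-composition
#'   covariance is computed internally) or a symmetric covariance matrix.
#' @param lambda L1 penalty on off-diagonal entries of \eqn{\Sigma};
#'   default 0.05 (suited to log-scale covariances of order 1; see
#'   \code{\link{select_lambda}} for a data-driven choice).
#' @param mu Initial ADMM augmented-Lagrangian parameter (adapted by residual
#'   balancing), default 1.
#' @param tol Convergence tolerance on the relative change of \eqn{\Sigma} and
#'   the objective between outer iterations, default 1e-6.
#' @param max_iter Outer iteration cap, default 500.
#' @param pseudocount Pseudocount used when \code{x} is a count table.
#' @param n Sample size; required only when \code{x} is a covariance matrix
#'   and bootstrap-free downstream pooling needs it.
#' @return An object of class \code{"cclasso"} with components \code{Sigma}
#'   (estimated latent covariance, symmetric, PSD within 1e-8, exact zeros
#'   where the penalty is active), \code{rho} (the latent correlation matrix),
#'   \code{b}, \code{objective} (trace across outer iterations),
#'   \code{converged}, \code{iterations}, \code{S}, \code{n}, \code{lambda}.
#' @examples
#' S <- diag(5)
#' fit <- cclasso(S, lambda = 0.01)
#' coef(fit)
#' @export
cclasso <- function(x, lambda = 0.05, mu = 1, tol = 1e-6, max_iter = 500,
                    pseudocount = 0.5, n = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && !is.null(rownames(x)) &&
      identical(rownames(x), colnames(x)) && isSymmetric(unname(x))) {
    S <- x
  } else if (nrow(x) != ncol(x) || !isSymmetric(unname(x))) {
    S <- log_composition_covariance(x, pseudocount)
    n <- nrow(x)
  } else {
    S <- x
  }
  stopifnot(lambda >= 0, mu > 0, tol > 0, max_iter >= 1)
  p <- ncol(S)
  ids <- colnames(S) %||% paste0("V", seq_len(p))
  dimnames(S) <- list(ids, ids)

  off_l1 <- function(Z) (sum(abs(Z)) - sum(abs(diag(Z)))) / 2
  obj_val <- function(Z, b) {
    R <- S - Z + outer(b, rep(1, p)) + outer(rep(1, p), b)
    0.5 * sum(R^2) + lambda * off_l1(Z)
  }

  # ADMM solve of: min_{Sigma >= 0} 0.5||A - Sigma||_F^2 + lambda*||offdiag||_1
  # split as Sigma (PSD block) = Z (soft-threshold block); warm-started.
  sigma_block <- function(A, Z, U, mu, inner_tol, inner_max = 500L) {
    for (k in seq_len(inner_max)) {
      Sig <- proj_psd((A + mu * (Z - U)) / (1 + mu))
      Z_old <- Z
      M <- Sig + U
      Z <- sign(M) * pmax(abs(M) - lambda / mu, 0)
      diag(Z) <- diag(M)
      U <- U + Sig - Z
      primal <- frob(Sig - Z)
      dual <- mu * frob(Z - Z_old)
      scale <- max(1, frob(Z))
      if (primal < inner_tol * scale && dual < inner_tol * scale) break
      if (primal > 10 * dual) {
        mu <- mu * 2; U <- U / 2
      } else if (dual > 10 * primal) {
        mu <- mu / 2; U <- U * 2
      }
    }
    list(Sigma = Sig, Z = Z, U = U, mu = mu)
  }

  one <- rep(1, p)
  b <- numeric(p)
  Z <- proj_psd(S)
  U <- matrix(0, p, p)
  obj <- obj_val(Z, b)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  inner_tol <- max(tol * 1e-2, 1e-10)
  repeat {
    iter <- iter + 1L
    # closed-form b-update given current Sigma estimate (Z): with D = Sigma - S,
    # b = (D 1 - s 1) / p, s = 1' D 1 / (2 p)
    D <- Z - S
    s <- sum(D) / (2 * p)
    b <- (as.vector(D %*% one) - s) / p
    A <- S + outer(b, one) + outer(one, b)
    obj_b <- obj_val(Z, b) # exact minimization over b: never above `obj`
    st <- sigma_block(A, Z, U, mu, inner_tol)
    # accept the Sigma-block update only if it does not increase the
    # objective (the inner ADMM is solved to finite tolerance); one retry at
    # a tighter tolerance, then stop at the current point
    if (obj_val(st$Z, b) > obj_b) {
      st <- sigma_block(A, st$Z, st$U, st$mu, inner_tol * 1e-3, 2000L)
      if (obj_val(st$Z, b) > obj_b) {
        trace <- c(trace, obj_b)
        obj <- obj_b
        converged <- TRUE
        break
      }
    }
    Z_prev <- Z
    Z <- st$Z; U <- st$U; mu <- st$mu
    obj_new <- obj_val(Z, b)
    trace <- c(trace, obj_new)
    delta <- frob(Z - Z_prev) / max(1, frob(Z))
    if (delta < tol && abs(obj - obj_new) < tol * max(1, abs(obj))) {
      converged <- TRUE
    }
    obj <- obj_new
    if (converged || iter >= max_iter) break
  }
  if (!converged) {
    warning("cclasso did not converge in ", max_iter, " iterations")
  }

  Sigma <- (Z + t(Z)) / 2
  # Exact zeros from the soft-threshold block are kept; a minimal diagonal
  # ridge lift restores PSD if the split left a tiny negative eigenvalue.
  me <- min_eigenvalue(Sigma)
  if (me < 0) {
    Sigma <- Sigma + diag(-me + 1e-12, p)
    me <- min_eigenvalue(Sigma)
  }
  d <- diag(Sigma)
  d[d <= 0] <- 1e-12
  rho <- Sigma / sqrt(outer(d, d))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(Sigma) <- dimnames(rho) <- list(ids, ids)

  structure(list(Sigma = Sigma, rho = rho, b = stats::setNames(b, ids),
                 lambda = lambda, mu = mu, tol = tol, max_iter = max_iter,
                 converged = converged, iterations = iter,
                 objective = trace, S = S, n = n, min_eig = me,
                 call = match.call()),
            class = "cclasso")
}

#' @export
print.cclasso <- function(x, ...) {
  p <- ncol(x$Sigma)
  nz <- sum(x$Sigma[upper.tri(x$Sigma)] != 0)
  cat("Latent correlation network (CCLasso-type penalized covariance)\n")
  cat(sprintf("  %d taxa%s, lambda = %g\n", p,
              if (!is.null(x$n)) sprintf(", n = %d", x$n) else "", x$lambda))
  cat(sprintf("  %d / %d nonzero off-diagonal entries; %s in %d iterations\n",
              nz, p * (p - 1) / 2,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @export
coef.cclasso <- function(object, type = c("correlation", "covariance"), ...) {
  type <- match.arg(type)
  if (type == "correlation") object$rho else object$Sigma
}

#' @export
fitted.cclasso <- function(object, ...) {
  p <- ncol(object$Sigma)
  one <- rep(1, p)
  object$Sigma - outer(object$b, one) - outer(one, object$b)
}

#' @export
residuals.cclasso <- function(object, ...) {
  object$S - fitted(object)
}

#' @export
summary.cclasso <- function(object, ...) {
  r <- object$rho[upper.tri(object$rho)]
  out <- list(
    p = ncol(object$Sigma), n = object$n, lambda = object$lambda,
    n_edges = sum(r != 0), n_positive = sum(r > 0), n_negative = sum(r < 0),
    max_abs_r = if (any(r != 0)) max(abs(r)) else 0,
    objective = utils::tail(object$objective, 1),
    converged = object$converged, iterations = object$iterations,
    min_eig = object$min_eig)
  class(out) <- "summary.cclasso"
  out
}

#' @export
print.summary.cclasso <- function(x, ...) {
  cat(sprintf("CCLasso fit: p = %d, lambda = %g\n", x$p, x$lambda))
  cat(sprintf("  nonzero edges: %d (%d positive, %d negative), max |r| = %.3f\n",
              x$n_edges, x$n_positive, x$n_negative, x$max_abs_r))
  cat(sprintf("  objective %.6g, %s (%d iterations), min eigenvalue %.2e\n",
              x$objective, if (x$converged) "converged" else "not converged",
              x$iterations, x$min_eig))
  invisible(x)
}

#' @export
plot.cclasso <- function(x, ...) {
  p <- ncol(x$rho)
  graphics::image(seq_len(p), seq_len(p), t(x$rho[p:1, , drop = FALSE]),
                  zlim = c(-1, 1),
                  col = grDevices::hcl.colors(51, "Blue-Red 3"),
                  xlab = "", ylab = "", axes = FALSE,
                  main = "Estimated latent correlations", ...)
  graphics::box()
  invisible(x)
}

#' Cross-validated penalty selection
#'
#' K-fold cross-validation over a grid of L1 penalties: for each fold the model
#' is fitted on the training samples and scored by the Frobenius loss between
#' the held-out log-composition covariance and the fitted
#' \eqn{\hat\Sigma - \hat b 1^T - 1 \hat b^T}. Ties are broken toward the
#' larger (sparser) penalty.
#'
#' @param counts Count matrix (samples x genera).
#' @param grid Positive penalty grid.
#' @param folds Number of folds, default 5.
#' @param seed Optional integer seed for the fold assignment.
#' @param ... Passed to \code{\link{cclasso}}.
#' @return The selected penalty (scalar), with the per-grid mean losses in
#'   attribute \code{"cv_loss"}.
#' @export
select_lambda <- function(counts, grid = c(0.01, 0.02, 0.05, 0.1, 0.2),
                          folds = 5, seed = NULL, ...) {
  counts <- as.matrix(counts)
  stopifnot(length(grid) >= 1, all(grid > 0))
  n <- nrow(counts)
  if (n < folds) stop("fewer samples (", n, ") than folds (", folds, ")")
  if (length(grid) == 1) return(grid)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  loss <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    train <- counts[fold_id != f, , drop = FALSE]
    test <- counts[fold_id == f, , drop = FALSE]
    if (nrow(test) < 2 || nrow(train) < 2) next
    S_test <- log_composition_covariance(test)
    for (g in seq_along(grid)) {
      fit <- cclasso(train, lambda = grid[g], ...)
      loss[f, g] <- sum((S_test - fitted(fit))^2)
    }
  }
  mean_loss <- colMeans(loss, na.rm = TRUE)
  best <- which(mean_loss <= min(mean_loss) + 1e-15)
  sel <- max(grid[best])
  attr(sel, "cv_loss") <- stats::setNames(mean_loss, grid)
  sel
}

#' Bootstrap edge significance for a CCLasso network
#'
#' Refits the estimator on \code{B} with-replacement resamples of the samples
#' and reports, per genus pair, the full-data point estimate, the bootstrap
#' standard error, and an add-one two-sided sign-based bootstrap p-value
#' \eqn{p = 2 \min(\#\{\rho^* \le 0\} + 1, \#\{\rho^* \ge 0\} + 1)/(B + 1)}.
#'
#' @param counts Count matrix for one stratum (samples x genera).
#' @param lambda Penalty passed to \code{\link{cclasso}} (held fixed across
#'   resamples).
#' @param B Number of bootstrap resamples, default 100.
#' @param seed Optional integer seed.
#' @param min_n Refuse strata smaller than this (default 20).
#' @param ... Further arguments to \code{\link{cclasso}}.
#' @return Data frame with columns genus_i, genus_j, r, se_boot, p_boot, n.
#' @export
bootstrap_edges <- function(counts, lambda = 0.05, B = 100, seed = NULL,
                            min_n = 20, ...) {
  counts <- as.matrix(counts)
  stopifnot(B >= 2)
  n <- nrow(counts)
  if (n < min_n) stop("stratum too small: n = ", n, " < ", min_n)
  fit <- cclasso(counts, lambda = lambda, ...)
  ut <- upper.tri(fit$rho)
  ids <- colnames(fit$rho)
  pairs <- which(ut, arr.ind = TRUE)
  point <- fit$rho[ut]
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cclasso(counts[idx, , drop = FALSE], lambda = lambda, ...)$rho[ut]
    }, numeric(sum(ut)))
  })
  boot <- matrix(boot, nrow = sum(ut))
  se <- apply(boot, 1, stats::sd)
  n_le <- rowSums(boot <= 0)
  n_ge <- rowSums(boot >= 0)
  p <- pmin(1, 2 * (pmin(n_le, n_ge) + 1) / (B + 1))
  data.frame(genus_i = ids[pairs[, 1]], genus_j = ids[pairs[, 2]],
             r = point, se_boot = se, p_boot = p, n = n,
             stringsAsFactors = FALSE)
}

#' Point-estimate edge table for one stratum
#'
#' Fits the latent-correlation estimator on one stratum's counts and returns
#' every genus pair's correlation with the stratum sample size — the input
#' rows for \code{\link{meta_network}}, which uses the Fisher-z variance
#' 1/(n - 3). Use \code{\link{bootstrap_edges}} instead when bootstrap
#' standard errors are wanted as QC.
#'
#' @param counts Count matrix for one stratum (samples x genera).
#' @param lambda Penalty passed to \code{\link{cclasso}}.
#' @param ... Further arguments to \code{\link{cclasso}}.
#' @return Data frame with columns genus_i, genus_j, r, n.
#' @export
stratum_edges <- function(counts, lambda = 0.05, ...) {
  fit <- cclasso(counts, lambda = lambda, ...)
  ut <- upper.tri(fit$rho)
  ids <- colnames(fit$rho)
  pairs <- which(ut, arr.ind = TRUE)
  data.frame(genus_i = ids[pairs[, 1]], genus_j = ids[pairs[, 2]],
             r = fit$rho[ut], n = nrow(counts), stringsAsFactors = FALSE)
}
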