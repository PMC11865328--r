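`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

frob <- function(m) sqrt(sum(m^2))

# Canonical unordered-pair key used everywhere edges are matched.
edge_key <- function(i, j) {
  paste(pmin(as.character(i), as.character(j)),
        pmax(as.character(i), as.character(j)),
        sep = "|")
}

#' Block-diagonal correlation matrix
#'
#' Builds a correlation matrix with consecutive blocks of equal within-block
#' correlation and zero between-block correlation. Used as the default planted
#' structure of the synthetic cohort generator.
#'
#' @param p Number of variables.
#' @param block_size Size of each block (the last block may be smaller).
#' @param rho Within-block correlation, in (-1, 1).
#' @return A \code{p x p} correlation matrix.
#' @export
block_correlation <- function(p, block_size = 4, rho = 0.45) {
  stopifnot(p >= 1, block_size >= 1, abs(rho) < 1)
  C <- diag(p)
  starts <- seq(1L, p, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, p)
    C[idx, idx] <- rho
  }
  diag(C) <- 1
  C
}

# Project a symmetric matrix onto the PSD cone (eigenvalue clipping at 0).
proj_psd <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  s <- e$vectors %*% (d * t(e$vectors))
  (s + t(s)) / 2
}

min_eigenvalue <- function(m) {
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# Clamp correlations strictly inside (-1, 1) so atanh stays finite.
clamp_r <- function(r, eps = 1e-7) pmin(pmax(r, -1 + eps), 1 - eps)
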