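#' Fisher z transform
#'
#' Variance-stabilizing transform of a correlation, \code{atanh(r)}; on this
#' scale a correlation estimated from \code{n} samples has approximate variance
#' \code{1/(n - 3)}.
#'
#' @param r Correlation(s) with |r| < 1.
#' @return \code{atanh(r)}.
#' @seealso \code{\link{inv_fisher_z}}
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher z transform")
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-z value(s).
#' @export
inv_fisher_z <- function(z) tanh(z)

#' DerSimonian-Laird random-effects pooling
#'
#' Pools effect estimates across strata with the classical moment estimator of
#' the between-stratum variance: with fixed weights \eqn{w = 1/v},
#' \eqn{Q = \sum w (z - \bar z_w)^2},
#' \eqn{\tau^2 = \max(0, (Q - (K-1)) / (\sum w - \sum w^2/\sum w))},
#' random-effects weights \eqn{w^* = 1/(v + \tau^2)}, pooled effect
#' \eqn{\sum w^* z / \sum w^*}, pooled SE \eqn{1/\sqrt{\sum w^*}}, two-sided
#' normal p, and \eqn{I^2 = \max(0, (Q - (K-1))/Q) \cdot 100}.
#'
#' @param z Effect estimates (e.g. Fisher-z correlations), length K >= 1.
#' @param v Within-stratum variances, same length, all positive.
#' @return List with pooled_z, pooled_se, p, tau2, Q, I2, K. For K = 1 the
#'   input is returned with tau2 = Q = I2 = 0.
#' @export
pool_random_effects <- function(z, v) {
  K <- length(z)
  if (K == 0) stop("no strata to pool")
  stopifnot(length(v) == K, all(v > 0), all(is.finite(z)))
  if (K == 1) {
    se <- sqrt(v)
    return(list(pooled_z = z, pooled_se = se,
                p = 2 * stats::pnorm(-abs(z / se)),
                tau2 = 0, Q = 0, I2 = 0, K = 1L))
  }
  w <- 1 / v
  zbar <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zbar)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (K - 1)) / denom)
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * z) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  I2 <- if (Q > 0) max(0, (Q - (K - 1)) / Q) * 100 else 0
  list(pooled_z = pooled, pooled_se = se,
       p = 2 * stats::pnorm(-abs(pooled / se)),
       tau2 = tau2, Q = Q, I2 = I2, K = as.integer(K))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR q-values: \eqn{q_i = \min_{j : p_{(j)} \ge p_{(i)}}
#' p_{(j)} m / j}, capped at 1.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Pool per-stratum co-abundance networks
#'
#' Combines per-stratum edge estimates (correlation r and sample size n per
#' genus pair) into one network by random-effects meta-analysis on the Fisher-z
#' scale with within-stratum variance 1/(n - 3), then applies BH FDR jointly
#' across all pooled edges.
#'
#' @param strata_edges Named list of per-stratum data frames with columns
#'   \code{genus_i}, \code{genus_j}, \code{r}, \code{n}.
#' @param fdr_threshold Significance threshold on the q-value, default 0.05.
#' @param k_min Minimum number of strata an edge must be estimable in to be
#'   pooled (default 2; automatically 1 when only one stratum is supplied).
#' @return Data frame with one row per pooled edge: genus_i, genus_j, K,
#'   pooled_r, pooled_z, se, tau2, Q, I2, p, q, significant.
#' @export
meta_network <- function(strata_edges, fdr_threshold = 0.05, k_min = 2) {
  stopifnot(length(strata_edges) >= 1)
  if (length(strata_edges) == 1) k_min <- 1L
  all_edges <- do.call(rbind, lapply(strata_edges, function(d) {
    d <- d[is.finite(d$r) & d$n > 3, , drop = FALSE]
    d
  }))
  key <- edge_key(all_edges$genus_i, all_edges$genus_j)
  split_idx <- split(seq_len(nrow(all_edges)), key)
  kept <- Filter(function(ix) length(ix) >= k_min, split_idx)
  n_drop <- length(split_idx) - length(kept)
  if (n_drop > 0) {
    message(n_drop, " edge(s) estimable in fewer than ", k_min,
            " strata excluded from pooling")
  }
  if (length(kept) == 0) stop("no edges estimable in enough strata")
  rows <- lapply(kept, function(ix) {
    d <- all_edges[ix, , drop = FALSE]
    z <- fisher_z(clamp_r(d$r))
    v <- 1 / (d$n - 3)
    pe <- pool_random_effects(z, v)
    data.frame(genus_i = pmin(d$genus_i[1], d$genus_j[1]),
               genus_j = pmax(d$genus_i[1], d$genus_j[1]),
               K = pe$K, pooled_r = inv_fisher_z(pe$pooled_z),
               pooled_z = pe$pooled_z, se = pe$pooled_se, tau2 = pe$tau2,
               Q = pe$Q, I2 = pe$I2, p = pe$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_threshold
  out[order(out$genus_i, out$genus_j), ]
}

#' Summaries of a significant co-abundance network
#'
#' Node and edge counts, mean degree (2E/N over all genera in the node set),
#' per-genus degree, per-phylum participation (a genus counts for its phylum;
#' an edge counts for every phylum with at least one endpoint in it), and the
#' percentage of negative edges.
#'
#' @param edges Data frame of edges with columns \code{genus_i},
#'   \code{genus_j} and a correlation column (\code{pooled_r} or \code{r}).
#' @param taxonomy Data frame with columns \code{genus}, \code{phylum}
#'   defining the node set.
#' @return List with n_nodes, n_edges, mean_degree, degree (named vector),
#'   pct_negative, phylum_genera / phylum_genera_pct, phylum_edges /
#'   phylum_edges_pct.
#' @export
network_summary <- function(edges, taxonomy) {
  stopifnot(all(c("genus", "phylum") %in% names(taxonomy)))
  rcol <- if ("pooled_r" %in% names(edges)) "pooled_r" else "r"
  N <- nrow(taxonomy)
  E <- nrow(edges)
  deg <- table(factor(c(edges$genus_i, edges$genus_j),
                      levels = taxonomy$genus))
  phy <- stats::setNames(as.character(taxonomy$phylum), taxonomy$genus)
  phyla <- sort(unique(as.character(taxonomy$phylum)))
  genus_in_net <- unique(c(edges$genus_i, edges$genus_j))
  phylum_genera <- vapply(phyla, function(ph)
    sum(phy[genus_in_net] == ph), integer(1))
  phylum_edges <- vapply(phyla, function(ph)
    sum(phy[edges$genus_i] == ph | phy[edges$genus_j] == ph), integer(1))
  list(
    n_nodes = N, n_edges = E, mean_degree = 2 * E / N,
    degree = c(deg),
    pct_negative = if (E > 0) 100 * mean(edges[[rcol]] < 0) else NA_real_,
    phylum_genera = phylum_genera,
    phylum_genera_pct = 100 * phylum_genera / max(1, length(genus_in_net)),
    phylum_edges = phylum_edges,
    phylum_edges_pct = if (E > 0) 100 * phylum_edges / E else phylum_edges)
}
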