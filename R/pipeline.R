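#' Pipeline configuration
#'
#' Bundles the thresholds and inputs of the end-to-end analysis. Either a
#' \code{\link{sim_config}} (synthetic cohort), a cohort directory written by
#' \code{\link{write_cohort}}, or an in-memory cohort object must be supplied.
#'
#' @param sim Optional \code{sim_config} for a synthetic cohort.
#' @param input_dir Optional cohort directory (counts/taxonomy/metadata/
#'   pathways TSVs).
#' @param cohort Optional in-memory \code{coabnet_cohort}.
#' @param out_dir Output directory; every stage writes its tables here.
#' @param depth Rarefaction depth, default 10000.
#' @param prevalence Prevalence filter fraction, default 0.10.
#' @param lambda L1 penalty or \code{"auto"} for cross-validated selection.
#' @param bootstrap_B Bootstrap resamples per stratum network (QC standard
#'   errors; 0 disables), default 100.
#' @param fdr FDR threshold for significant edges, default 0.05.
#' @param i2_threshold,het_p Heterogeneity thresholds (I-squared percent and
#'   Q-test p), defaults 75 and 0.05.
#' @param trend_p Severity / variance trend threshold, default 0.05.
#' @param stratum_floor Minimum stratum sample size, default 20.
#' @param grade_mode \code{"stratified"} or \code{"combined"} for the
#'   per-grade networks.
#' @param seed Integer seed driving every stochastic stage.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL, cohort = NULL,
                            out_dir = tempfile("coabnet_run_"),
                            depth = 10000, prevalence = 0.10, lambda = 0.05,
                            bootstrap_B = 100, fdr = 0.05, i2_threshold = 75,
                            het_p = 0.05, trend_p = 0.05, stratum_floor = 20,
                            grade_mode = c("stratified", "combined"),
                            seed = 1) {
  grade_mode <- match.arg(grade_mode)
  if (is.null(sim) && is.null(input_dir) && is.null(cohort)) {
    stop("one of sim, input_dir or cohort must be given")
  }
  stopifnot(depth > 0, prevalence > 0, prevalence <= 1,
            fdr > 0, fdr < 1, i2_threshold >= 0, i2_threshold <= 100,
            het_p > 0, het_p < 1, trend_p > 0, trend_p < 1,
            stratum_floor >= 4, bootstrap_B >= 0)
  if (!identical(lambda, "auto")) stopifnot(is.numeric(lambda), lambda >= 0)
  structure(list(sim = sim, input_dir = input_dir, cohort = cohort,
                 out_dir = out_dir, depth = depth, prevalence = prevalence,
                 lambda = lambda, bootstrap_B = bootstrap_B, fdr = fdr,
                 i2_threshold = i2_threshold, het_p = het_p,
                 trend_p = trend_p, stratum_floor = stratum_floor,
                 grade_mode = grade_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Inverse-rank transform + covariate residualization of a relative-abundance
# (or pathway) matrix; the global transform applied before rank tests,
# partial correlations and interaction models.
transform_abundances <- function(values, metadata,
                                 covariate_cols = c("age", "sex", "bmi",
                                   "smoking", "antibiotics", "diabetes",
                                   "hypercholesterolemia", "obesity")) {
  values <- as.matrix(values)
  X <- as.matrix(metadata[, covariate_cols])
  out <- matrix(NA_real_, nrow(values), ncol(values),
                dimnames = dimnames(values))
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    out[, j] <- if (max(v) == min(v)) 0 else
      residualize(inverse_rank_transform(v), X)
  }
  out
}

#' Run the full co-abundance analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation or file input),
#' rarefaction and prevalence filtering, per-region-by-group network
#' inference, random-effects meta-analysis per group, differential network
#' detection between groups, covariate adjustment of differential edges by
#' partial correlation, per-grade networks with grade-heterogeneity and
#' severity trends, differential abundance of genera and pathways with the
#' pathway funnel, and the genus-pair interaction-variance scan. Every
#' stage's tables are written to \code{out_dir} before the next stage begins;
#' identical config and seed produce bit-identical outputs.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return A \code{coabnet_report} list of stage tallies (invisibly also
#'   carrying the stage tables in attribute \code{"tables"}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("data", {
    if (!is.null(cfg$cohort)) cfg$cohort
    else if (!is.null(cfg$sim)) simulate_cohort(cfg$sim)
    else read_cohort(cfg$input_dir)
  })
  writeLines(jsonlite::serializeJSON(cfg[setdiff(names(cfg),
                                                 c("cohort", "out_dir"))],
                                     digits = I(17)),
             file.path(cfg$out_dir, "config.json"))

  filtered <- stage("rarefy_filter", {
    counts <- rarefy(cohort$counts, cfg$depth, seed = cfg$seed + 1L)
    md <- cohort$metadata[match(rownames(counts), cohort$metadata$sample_id),
                          , drop = FALSE]
    counts <- prevalence_filter(counts, cfg$prevalence)
    tax <- cohort$taxonomy[cohort$taxonomy$genus %in% colnames(counts),
                           , drop = FALSE]
    pw <- cohort$pathways[rownames(counts), , drop = FALSE]
    write_matrix_tsv(counts, file.path(cfg$out_dir, "counts_filtered.tsv"))
    list(counts = counts, metadata = md, taxonomy = tax, pathways = pw)
  })
  counts <- filtered$counts
  md <- filtered$metadata

  lambda <- stage("lambda", {
    if (identical(cfg$lambda, "auto"))
      as.numeric(select_lambda(counts, seed = cfg$seed + 2L))
    else cfg$lambda
  })

  networks <- stage("stratum_networks", {
    out <- list()
    for (grp in c("case", "control")) {
      sel <- if (grp == "case") md$hypertension else !md$hypertension
      strata <- list()
      regions <- sort(unique(md$region[sel]))
      for (k in seq_along(regions)) {
        idx <- which(sel & md$region == regions[k])
        if (length(idx) < cfg$stratum_floor) next
        sub <- counts[idx, , drop = FALSE]
        strata[[regions[k]]] <- if (cfg$bootstrap_B >= 2) {
          bootstrap_edges(sub, lambda = lambda, B = cfg$bootstrap_B,
                          seed = cfg$seed + 10L + k +
                            1000L * (grp == "case"),
                          min_n = cfg$stratum_floor)
        } else {
          stratum_edges(sub, lambda = lambda)
        }
      }
      if (length(strata) == 0) stop("no usable stratum for group ", grp)
      edges <- do.call(rbind, Map(cbind, strata,
                                  stratum = names(strata)))
      write_tsv(edges, file.path(cfg$out_dir,
                                 paste0("edges_", grp, ".tsv")))
      out[[grp]] <- strata
    }
    out
  })

  metas <- stage("meta", {
    m <- lapply(networks, meta_network, fdr_threshold = cfg$fdr)
    write_tsv(m$case, file.path(cfg$out_dir, "meta_case.tsv"))
    write_tsv(m$control, file.path(cfg$out_dir, "meta_control.tsv"))
    for (grp in names(m)) {
      sig <- m[[grp]][m[[grp]]$significant, , drop = FALSE]
      if (nrow(sig) > 0) {
        export_graphml(sig, file.path(cfg$out_dir,
                                      paste0("network_", grp, ".graphml")))
      }
    }
    m
  })

  diff <- stage("differential", {
    d <- differential_network(metas$case, metas$control,
                              i2_threshold = cfg$i2_threshold,
                              p_threshold = cfg$het_p)
    write_tsv(d, file.path(cfg$out_dir, "differential_edges.tsv"))
    d
  })
  het_edges <- diff[diff$heterogeneous, , drop = FALSE]

  genus_res <- transform_abundances(
    sweep(counts, 1, rowSums(counts), "/"), md)

  adjusted <- stage("adjust", {
    if (nrow(het_edges) == 0) {
      list(consistency = NULL, n_consistent = 0L, pct_consistent = NA_real_)
    } else {
      sel <- md$hypertension
      regions <- sort(unique(md$region[sel]))
      ab <- cv <- list()
      for (r in regions) {
        idx <- which(sel & md$region == r)
        if (length(idx) < cfg$stratum_floor) next
        ab[[r]] <- genus_res[idx, , drop = FALSE]
        cv[[r]] <- as.matrix(md[idx, c("age", "sex", "bmi", "smoking",
                                       "antibiotics", "diabetes",
                                       "hypercholesterolemia", "obesity")])
      }
      adj_strata <- adjust_partial_correlation(het_edges, ab, cv)
      adj_meta <- meta_network(adj_strata, fdr_threshold = cfg$fdr)
      cons <- edge_consistency(metas$case, adj_meta, p_threshold = cfg$het_p)
      write_tsv(cons, file.path(cfg$out_dir, "adjusted_consistency.tsv"))
      list(consistency = cons, n_consistent = sum(cons$consistent),
           pct_consistent = 100 * mean(cons$consistent))
    }
  })

  severity <- stage("severity", {
    if (nrow(het_edges) == 0) {
      NULL
    } else {
      gm <- grade_networks(counts, md, lambda = lambda,
                           min_stratum_n = cfg$stratum_floor,
                           mode = cfg$grade_mode)
      sev <- severity_edges(het_edges, gm, i2_threshold = cfg$i2_threshold,
                            p_threshold = cfg$het_p,
                            trend_p_threshold = cfg$trend_p)
      write_tsv(sev, file.path(cfg$out_dir, "severity_edges.tsv"))
      sev
    }
  })

  abundance <- stage("differential_abundance", {
    da_genus <- differential_abundance(counts, md, "two_group")
    da_pw2 <- differential_abundance(filtered$pathways, md, "two_group")
    da_pw4 <- differential_abundance(filtered$pathways, md, "four_grade")
    write_tsv(da_genus, file.path(cfg$out_dir, "da_genera.tsv"))
    write_tsv(da_pw2, file.path(cfg$out_dir, "da_pathways_group.tsv"))
    write_tsv(da_pw4, file.path(cfg$out_dir, "da_pathways_grade.tsv"))
    list(genus = da_genus, pw2 = da_pw2, pw4 = da_pw4,
         screened = pathway_screen(da_pw2, da_pw4, cfg$fdr))
  })

  interaction <- stage("interaction_variance", {
    pairs <- if (!is.null(severity) && any(severity$severity_associated)) {
      severity[severity$severity_associated, c("genus_i", "genus_j")]
    } else if (nrow(het_edges) > 0) {
      het_edges[, c("genus_i", "genus_j")]
    } else NULL
    if (is.null(pairs) || length(abundance$screened) == 0) {
      list(fits = NULL, trends = NULL)
    } else {
      pw_res <- transform_abundances(
        filtered$pathways[, abundance$screened, drop = FALSE], md)
      sc <- interaction_scan(pw_res, genus_res, pairs, md$grade)
      if (!is.null(sc$fits)) {
        write_tsv(sc$fits, file.path(cfg$out_dir, "interaction_fits.tsv"))
        write_tsv(sc$trends, file.path(cfg$out_dir,
                                       "interaction_trends.tsv"))
      }
      sc
    }
  })

  ov <- edge_overlap(metas$case[metas$case$significant, , drop = FALSE],
                     metas$control[metas$control$significant, , drop = FALSE])
  class_tab <- if (nrow(het_edges) > 0) table(het_edges$class) else table(NULL)
  report <- list(
    seed = cfg$seed, lambda = lambda,
    n_samples = nrow(counts), n_genera = ncol(counts),
    n_edges_case = sum(metas$case$significant),
    n_edges_control = sum(metas$control$significant),
    edge_overlap = ov,
    n_differential = nrow(het_edges),
    differential_classes = as.list(class_tab),
    pct_classes = if (nrow(het_edges) > 0)
      as.list(round(100 * prop.table(class_tab), 1)) else list(),
    adjusted_consistent = adjusted$n_consistent,
    adjusted_pct_consistent = adjusted$pct_consistent,
    n_grade_heterogeneous = if (!is.null(severity))
      sum(severity$grade_heterogeneous) else 0L,
    n_severity_associated = if (!is.null(severity))
      sum(severity$severity_associated) else 0L,
    n_pathways_screened = length(abundance$screened),
    n_interaction_fits = if (!is.null(interaction$fits))
      nrow(interaction$fits) else 0L,
    n_interaction_significant = if (!is.null(interaction$fits))
      sum(interaction$fits$q < cfg$fdr, na.rm = TRUE) else 0L,
    n_variance_trend_significant = if (!is.null(interaction$trends))
      sum(interaction$trends$p_trend < cfg$trend_p, na.rm = TRUE) else 0L)
  class(report) <- "coabnet_report"
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, null = "null"),
             file.path(cfg$out_dir, "report.json"))
  attr(report, "tables") <- list(meta = metas, differential = diff,
                                 severity = severity, abundance = abundance,
                                 interaction = interaction,
                                 adjusted = adjusted)
  report
}

#' @export
print.coabnet_report <- function(x, ...) {
  cat("Co-abundance pipeline report\n")
  cat(sprintf("  %d samples x %d genera (lambda = %g, seed %d)\n",
              x$n_samples, x$n_genera, x$lambda, x$seed))
  cat(sprintf("  significant edges: case %d, control %d, union %d\n",
              x$n_edges_case, x$n_edges_control, x$edge_overlap$union))
  cat(sprintf("  differential edges: %d", x$n_differential))
  if (length(x$pct_classes) > 0) {
    cat(" (", paste(sprintf("%s %.1f%%", names(x$pct_classes),
                            unlist(x$pct_classes)), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  cat(sprintf("  grade-heterogeneous: %d; severity-associated: %d\n",
              x$n_grade_heterogeneous, x$n_severity_associated))
  cat(sprintf("  screened pathways: %d; interaction F-tests: %d (%d at FDR); trend-significant: %d\n",
              x$n_pathways_screened, x$n_interaction_fits,
              x$n_interaction_significant, x$n_variance_trend_significant))
  invisible(x)
}

#' Overlap of two edge sets
#'
#' Edges are keyed by the unordered genus pair; standard set algebra with
#' \code{|A union B| = |A| + |B| - |A intersect B|}.
#'
#' @param a,b Edge data frames (genus_i, genus_j) or character vectors of
#'   precomputed edge keys.
#' @return List with sizes: a, b, intersection, union.
#' @export
edge_overlap <- function(a, b) {
  key_of <- function(x) {
    if (is.character(x)) unique(x)
    else unique(edge_key(x$genus_i, x$genus_j))
  }
  ka <- key_of(a); kb <- key_of(b)
  ni <- length(intersect(ka, kb))
  list(a = length(ka), b = length(kb), intersection = ni,
       union = length(ka) + length(kb) - ni)
}
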