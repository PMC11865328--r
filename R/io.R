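#' Write / read tab-separated tables
#'
#' TSV writer/reader pair used for every stage output. Numeric columns are
#' written with 17 significant digits so tables round-trip bit-exact through
#' write then read.
#'
#' @param x Data frame.
#' @param path File path.
#' @return \code{read_tsv} returns a data frame; \code{write_tsv} returns
#'   \code{path} invisibly.
#' @export
write_tsv <- function(x, path) {
  x <- as.data.frame(x)
  fmt <- x
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) && all(df[[j]] %in% c("TRUE", "FALSE"))) {
      df[[j]] <- as.logical(df[[j]])
    }
  }
  df
}

#' Write / read a count (or pathway) matrix as TSV
#'
#' Samples as rows; the first column holds the sample ID.
#'
#' @param m Matrix with row and column names.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Serialize / restore a ground-truth manifest
#'
#' The manifest (planted correlation matrices, edge lists, pathway
#' coefficients, latent values) is stored with \code{jsonlite::serializeJSON},
#' which round-trips R doubles losslessly.
#'
#' @param manifest Manifest list from \code{\link{simulate_cohort}}.
#' @param path File path (.json).
#' @export
write_manifest <- function(manifest, path) {
  writeLines(jsonlite::serializeJSON(manifest, digits = I(17)), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Write a cohort to a directory of plain-text files
#'
#' Counts, taxonomy, metadata and pathway tables as TSV plus the manifest as
#' JSON.
#'
#' @param cohort A \code{coabnet_cohort}.
#' @param dir Output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  write_tsv(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_matrix_tsv(cohort$pathways, file.path(dir, "pathways.tsv"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  counts <- read_matrix_tsv(file.path(dir, "counts.tsv"))
  storage.mode(counts) <- "integer"
  structure(list(
    counts = counts,
    taxonomy = read_tsv(file.path(dir, "taxonomy.tsv")),
    metadata = read_tsv(file.path(dir, "metadata.tsv")),
    pathways = read_matrix_tsv(file.path(dir, "pathways.tsv")),
    manifest = if (file.exists(file.path(dir, "manifest.json")))
      read_manifest(file.path(dir, "manifest.json")) else NULL),
    class = "coabnet_cohort")
}

#' Export an edge table as GraphML
#'
#' Writes the network (one node per genus, the correlation as edge weight)
#' in GraphML via igraph for use in external network viewers.
#'
#' @param edges Data frame with genus_i, genus_j and a correlation column
#'   (\code{pooled_r} or \code{r}).
#' @param path Output file.
#' @export
export_graphml <- function(edges, path) {
  rcol <- if ("pooled_r" %in% names(edges)) "pooled_r" else "r"
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$genus_i, to = edges$genus_j,
               weight = edges[[rcol]]),
    directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
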