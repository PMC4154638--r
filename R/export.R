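#' Write a residue-labelled square matrix as CSV
#'
#' @param m Square matrix.
#' @param path Output path.
#' @param labels Row/column labels (default: existing dimnames or indices).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, labels = NULL) {
  m <- as.matrix(m)
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' Write a plain-text square matrix (xPyder-compatible .dat)
#'
#' Whitespace-separated numeric square matrix with no headers.
#'
#' @inheritParams write_matrix_csv
#' @return `path`, invisibly.
#' @export
write_matrix_dat <- function(m, path) {
  utils::write.table(as.matrix(m), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert a network to an igraph object
#'
#' @param x A `psn` or `metagraph`.
#' @return An igraph graph with a `weight` edge attribute.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "psn")) {
    g <- igraph::graph_from_data_frame(
      x$edges[, c("i", "j", "weight")], directed = FALSE,
      vertices = data.frame(name = seq_along(x$degrees), label = x$labels)
    )
  } else if (inherits(x, "metagraph")) {
    verts <- data.frame(name = x$nodes$residue, participation = x$nodes$participation)
    g <- igraph::graph_from_data_frame(
      x$edges[, c("i", "j", "weight")], directed = FALSE, vertices = verts
    )
  } else {
    abort_invalid("cannot convert this object to igraph")
  }
  g
}

#' Write a network as GML or DOT
#'
#' @param x A `psn` or `metagraph`.
#' @param path Output path.
#' @param format `"gml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(x, path, format = c("gml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(x), path, format = format)
  if (format == "gml") {
    # igraph stamps a timestamped Creator comment; normalize it so that
    # identical runs produce byte-identical artifacts
    lines <- readLines(path, warn = FALSE)
    lines[startsWith(lines, "Creator")] <- "Creator \"psnpaths\""
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write retained paths as JSON
#'
#' Node lists are reported with both internal indices and residue labels.
#'
#' @param paths Path tibble from [paths_to_targets()].
#' @param path Output path.
#' @param labels Optional residue labels (author numbering).
#' @return `path`, invisibly.
#' @export
write_paths_json <- function(paths, path, labels = NULL) {
  recs <- lapply(seq_len(nrow(paths)), function(k) {
    nodes <- paths$nodes[[k]]
    list(
      source = paths$source[k], target = paths$target[k],
      nodes = nodes,
      labels = if (!is.null(labels)) labels[nodes] else NULL,
      node_count = paths$node_count[k], hop_length = paths$hop_length[k],
      occurrence = paths$occurrence[k], correlation_ok = paths$correlation_ok[k]
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
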