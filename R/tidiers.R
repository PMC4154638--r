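#' Tidy a protein structure network
#'
#' @param x A `psn`.
#' @param ... Unused.
#' @return Edge tibble (`i`, `j`, `weight`, and `persistence` for consensus
#'   networks).
#' @export
tidy.psn <- function(x, ...) x$edges

#' @rdname tidy.psn
#' @return [glance.psn()]: one-row summary tibble.
#' @export
glance.psn <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$degrees),
    n_edges = nrow(x$edges),
    n_orphans = sum(x$degrees == 0),
    n_clusters = length(unique(stats::na.omit(x$clusters))),
    largest_cluster = largest_cluster_size(x),
    i_min = x$i_min
  )
}

#' Tidy a windowed correlation set into long form
#'
#' @param x An `lmi_set`.
#' @param ... Unused.
#' @return Tibble with `window`, `i`, `j`, `r` for all residue pairs
#'   (upper triangle), including the `"average"` window.
#' @export
tidy.lmi_set <- function(x, ...) {
  one <- function(m, w) {
    ut <- which(upper.tri(m), arr.ind = TRUE)
    tibble::tibble(window = w, i = ut[, 1], j = ut[, 2], r = m[ut])
  }
  dplyr::bind_rows(
    purrr::imap(x$windows, function(m, w) one(m, as.character(w))),
    one(x$average, "average")
  )
}

#' @rdname tidy.lmi_set
#' @export
glance.lmi_set <- function(x, ...) {
  off <- x$average[upper.tri(x$average)]
  tibble::tibble(
    n_windows = x$n_windows, window_frames = x$window_frames,
    mean_r = mean(off), max_r = max(off),
    frac_significant = mean(off >= 0.5)
  )
}

#' Tidy a meta-graph
#'
#' @param x A `metagraph`.
#' @param ... Unused.
#' @return The occurrence-weighted edge tibble.
#' @export
tidy.metagraph <- function(x, ...) x$edges

#' @rdname tidy.metagraph
#' @export
glance.metagraph <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges), n_paths = x$n_paths,
    top_mediator = x$nodes$residue[1],
    top_participation = x$nodes$participation[1]
  )
}

#' Tidy a replicate-consistency report
#'
#' @param x A `replicate_consistency`.
#' @param ... Unused.
#' @return Long tibble of all Frobenius norms with a `comparison` column
#'   (`"pairwise"`, `"vs_control"`, `"baseline"`).
#' @export
tidy.replicate_consistency <- function(x, ...) {
  out <- dplyr::bind_rows(
    dplyr::mutate(x$pairwise, comparison = "pairwise"),
    dplyr::mutate(x$vs_control, comparison = "vs_control")
  )
  if (!is.null(x$baseline)) {
    out <- dplyr::bind_rows(out, dplyr::mutate(x$baseline, comparison = "baseline"))
  }
  out
}

#' @rdname tidy.replicate_consistency
#' @export
glance.replicate_consistency <- function(x, ...) {
  tibble::tibble(
    max_pairwise = max(x$pairwise$frobenius),
    min_vs_control = min(x$vs_control$frobenius),
    mean_baseline = if (!is.null(x$baseline)) mean(x$baseline$frobenius) else NA_real_,
    consistent = x$consistent
  )
}
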