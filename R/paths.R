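#' All-pairs shortest communication paths on a network
#'
#' Computes hop distances between every pair of nodes with the
#' Floyd-Warshall algorithm, treating every edge as unit length: the
#' shortest path between two residues is the one with the fewest
#' intermediate nodes. Unreachable pairs have infinite distance. Path
#' reconstruction is done on demand from the distance matrix:
#' [shortest_path()] returns one canonical path per pair (the
#' lexicographically smallest node sequence among all co-shortest paths)
#' and [enumerate_shortest_paths()] lists all equal-length shortest paths
#' up to a bound.
#'
#' @param psn A `psn` object (at least 2 nodes).
#' @return A `psn_paths` object: `dist` (hop-distance matrix) and
#'   `adjacency`.
#' @export
all_pairs_shortest_paths <- function(psn) {
  adj <- psn$adjacency
  n <- nrow(adj)
  if (n < 2) abort_invalid("graph needs at least 2 nodes")
  D <- matrix(Inf, n, n)
  D[adj] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    # vectorized relaxation through node k
    via <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, via)
  }
  structure(list(dist = D, adjacency = adj, labels = psn$labels),
            class = "psn_paths")
}

#' @export
print.psn_paths <- function(x, ...) {
  finite <- is.finite(x$dist[upper.tri(x$dist)])
  cat(sprintf("<psn_paths> %d nodes, %d reachable pairs (max distance %s)\n",
              nrow(x$dist), sum(finite),
              if (any(finite)) max(x$dist[upper.tri(x$dist)][finite]) else "-"))
  invisible(x)
}

#' @rdname all_pairs_shortest_paths
#' @param paths A `psn_paths` object.
#' @param from,to Node indices.
#' @return [shortest_path()]: integer vector of node indices (including the
#'   endpoints), or `NULL` if unreachable.
#' @export
shortest_path <- function(paths, from, to) {
  D <- paths$dist
  if (!is.finite(D[from, to])) return(NULL)
  if (from == to) return(from)
  out <- from
  u <- from
  while (u != to) {
    nbrs <- which(paths$adjacency[u, ])
    nxt <- nbrs[D[nbrs, to] == D[u, to] - 1]
    u <- min(nxt)  # lexicographically smallest canonical path
    out <- c(out, u)
  }
  out
}

#' @rdname all_pairs_shortest_paths
#' @param max_paths Enumeration bound (default 10^4); enumeration stops with
#'   a warning when exceeded.
#' @return [enumerate_shortest_paths()]: list of node-index vectors.
#' @export
enumerate_shortest_paths <- function(paths, from, to, max_paths = 1e4) {
  D <- paths$dist
  if (!is.finite(D[from, to])) return(list())
  acc <- list()
  truncated <- FALSE
  recurse <- function(prefix, u) {
    if (truncated) return()
    if (u == to) {
      acc[[length(acc) + 1L]] <<- prefix
      if (length(acc) >= max_paths) truncated <<- TRUE
      return()
    }
    nbrs <- which(paths$adjacency[u, ])
    for (v in sort(nbrs[D[nbrs, to] == D[u, to] - 1])) {
      recurse(c(prefix, v), v)
    }
  }
  recurse(from, from)
  if (truncated) warning("shortest-path enumeration truncated at ", max_paths, call. = FALSE)
  acc
}

#' Correlation filter for a communication path
#'
#' A path is retained when at least one of its intermediate nodes is
#' significantly correlated (generalized correlation at or above `cutoff`)
#' with the path's first or last residue. A direct edge has no
#' intermediates and cannot satisfy the rule; it returns `FALSE` and is
#' handled separately by [paths_to_targets()].
#'
#' @param nodes Integer vector of path node indices (endpoints included).
#' @param lmi Correlation matrix covering all path nodes.
#' @param cutoff Significance cutoff, default 0.5 (inclusive).
#' @return Logical.
#' @export
correlation_filter <- function(nodes, lmi, cutoff = 0.5) {
  if (length(nodes) < 3) return(FALSE)
  inter <- nodes[-c(1, length(nodes))]
  ends <- nodes[c(1, length(nodes))]
  any(lmi[inter, ends, drop = FALSE] >= cutoff)
}

#' Occurrence probability of a path across window networks
#'
#' Fraction of the per-window networks in which every consecutive edge of
#' the path is simultaneously present.
#'
#' @param nodes Integer vector of path node indices.
#' @param window_graphs List of `psn` objects, one per analysis window.
#' @return Fraction in `[0, 1]`.
#' @export
path_occurrence <- function(nodes, window_graphs) {
  if (length(window_graphs) < 1) abort_invalid("need at least one window graph")
  if (length(nodes) < 2) return(1)
  steps <- cbind(nodes[-length(nodes)], nodes[-1])
  mean(vapply(window_graphs, function(g) all(g$adjacency[steps]), logical(1)))
}

#' Correlation-filtered shortest paths from every residue to a target set
#'
#' For every residue outside the target set, finds the canonical shortest
#' path to each target residue on the consensus network, then applies the
#' selection cascade: the correlation filter (an intermediate node
#' significantly correlated with an endpoint), a minimum occurrence
#' probability across the window networks, and a minimum node count that
#' restricts attention to genuinely long-range communication. One path is
#' kept per source residue: the shortest, then highest-occurrence,
#' candidate over the target set. Direct source-target edges (no
#' intermediate node) are excluded from the ranking -- they are short-range
#' by construction -- and reported in the `direct_edges` attribute.
#'
#' @param psn Consensus `psn`.
#' @param lmi Correlation matrix (typically the window-averaged one).
#' @param window_graphs List of per-window `psn` objects for occurrence.
#' @param targets Integer vector of target residue indices (nonempty).
#' @param min_occurrence Minimum occurrence probability (default 0.15).
#' @param min_node_count Minimum number of path nodes, endpoints included
#'   (default 4, i.e. paths of length greater than three).
#' @param lmi_cutoff Correlation significance cutoff (default 0.5).
#' @return Tibble with one row per retained path: `source`, `target`,
#'   `nodes` (list column), `node_count`, `hop_length`, `occurrence`,
#'   `correlation_ok`; sorted by occurrence descending then hop length.
#'   Attribute `direct_edges` lists the source-target pairs joined by a
#'   direct edge.
#' @export
paths_to_targets <- function(psn, lmi, window_graphs, targets,
                             min_occurrence = 0.15, min_node_count = 4,
                             lmi_cutoff = 0.5) {
  if (length(targets) == 0) abort_invalid("`targets` must be nonempty")
  n <- nrow(psn$adjacency)
  if (any(targets < 1 | targets > n)) abort_invalid("targets outside the graph")
  ap <- all_pairs_shortest_paths(psn)
  sources <- setdiff(seq_len(n), targets)
  rows <- list()
  direct <- list()
  for (s in sources) {
    cands <- list()
    for (t in targets) {
      nodes <- shortest_path(ap, s, t)
      if (is.null(nodes)) next
      if (length(nodes) == 2) {
        direct[[length(direct) + 1L]] <- tibble::tibble(source = s, target = t)
        next
      }
      occ <- path_occurrence(nodes, window_graphs)
      ok <- correlation_filter(nodes, lmi, lmi_cutoff)
      if (!ok) next
      if (occ < min_occurrence) next
      if (length(nodes) < min_node_count) next
      nc <- length(nodes)
      cands[[length(cands) + 1L]] <- tibble::tibble(
        source = s, target = as.integer(t), nodes = list(nodes),
        node_count = nc, hop_length = nc - 1L,
        occurrence = occ, correlation_ok = ok
      )
    }
    if (length(cands) > 0) {
      cand <- dplyr::bind_rows(cands)
      cand <- cand[order(cand$hop_length, -cand$occurrence, cand$target), ]
      rows[[length(rows) + 1L]] <- cand[1, ]
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty_paths_tibble()
  out <- out[order(-out$occurrence, out$hop_length, out$source), ]
  attr(out, "direct_edges") <- if (length(direct) > 0) {
    dplyr::bind_rows(direct)
  } else {
    tibble::tibble(source = integer(0), target = integer(0))
  }
  out
}

empty_paths_tibble <- function() {
  tibble::tibble(
    source = integer(0), target = integer(0), nodes = list(),
    node_count = integer(0), hop_length = integer(0),
    occurrence = numeric(0), correlation_ok = logical(0)
  )
}

#' Partition paths into long-range and shorter classes
#'
#' Long-range paths span at least `min_nodes` residues, starting and final
#' residues included.
#'
#' @param paths Path tibble from [paths_to_targets()].
#' @param min_nodes Node count defining the long-range class (default 8).
#' @return List with `long_range` and `shorter` path tibbles and
#'   `histogram`, the per-node-count path counts.
#' @export
classify_long_range <- function(paths, min_nodes = 8) {
  is_long <- paths$node_count >= min_nodes
  histogram <- dplyr::count(paths, .data$node_count, name = "n_paths")
  list(
    long_range = paths[is_long, , drop = FALSE],
    shorter = paths[!is_long, , drop = FALSE],
    histogram = histogram
  )
}

#' Compare two path sets
#'
#' Paths are matched by their exact node sequence. The summary reports the
#' set sizes and the relative change in path count from A to B -- the
#' quantity behind statements like "a 28% decrease of long-range paths"
#' when applied to long-range subsets of two conditions.
#'
#' @param set_a,set_b Path tibbles (e.g. from [paths_to_targets()] or a
#'   [classify_long_range()] component).
#' @return List with `only_a`, `only_b`, `shared` tibbles and a `summary`
#'   tibble (`n_a`, `n_b`, `n_shared`, `n_only_a`, `n_only_b`,
#'   `relative_change`).
#' @export
compare_path_sets <- function(set_a, set_b) {
  key <- function(p) vapply(p$nodes, paste, character(1), collapse = "-")
  ka <- key(set_a); kb <- key(set_b)
  out <- list(
    only_a = set_a[!(ka %in% kb), , drop = FALSE],
    only_b = set_b[!(kb %in% ka), , drop = FALSE],
    shared = set_a[ka %in% kb, , drop = FALSE]
  )
  out$summary <- tibble::tibble(
    n_a = nrow(set_a), n_b = nrow(set_b), n_shared = nrow(out$shared),
    n_only_a = nrow(out$only_a), n_only_b = nrow(out$only_b),
    relative_change = if (nrow(set_a) > 0) (nrow(set_b) - nrow(set_a)) / nrow(set_a) else NA_real_
  )
  out
}

#' Join retained paths into an occurrence-weighted meta-graph
#'
#' All retained paths are merged into a single graph whose edge weights are
#' the probability of finding the same connection across the different
#' communication paths: weight = (number of paths containing the edge) /
#' (total paths). Per-node participation counts rank mediator residues --
#' the nodes through which communication is funnelled.
#'
#' @param paths Path tibble with at least one row.
#' @return A `metagraph`: `edges` (tibble `i`, `j`, `n_paths`, `weight`),
#'   `nodes` (tibble `residue`, `participation`), `n_paths`.
#' @export
build_metagraph <- function(paths) {
  if (nrow(paths) == 0) abort_invalid("cannot build a meta-graph from zero paths")
  total <- nrow(paths)
  edge_keys <- list()
  node_count <- integer(0)
  edge_count <- new.env(parent = emptyenv())
  for (p in paths$nodes) {
    for (k in seq_len(length(p) - 1L)) {
      a <- min(p[k], p[k + 1L]); b <- max(p[k], p[k + 1L])
      key <- paste(a, b)
      cur <- if (is.null(edge_count[[key]])) 0L else edge_count[[key]]
      edge_count[[key]] <- cur + 1L
    }
    for (v in unique(p)) {
      node_count[as.character(v)] <- sum(node_count[as.character(v)], 1L, na.rm = TRUE)
    }
  }
  keys <- ls(edge_count)
  parts <- do.call(rbind, strsplit(keys, " "))
  counts <- unname(vapply(keys, function(k) edge_count[[k]], integer(1)))
  edges <- tibble::tibble(
    i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
    n_paths = counts,
    weight = counts / total
  )
  edges <- edges[order(-edges$weight, edges$i, edges$j), ]
  nodes <- tibble::tibble(
    residue = as.integer(names(node_count)),
    participation = as.integer(node_count)
  )
  nodes <- nodes[order(-nodes$participation, nodes$residue), ]
  structure(list(edges = edges, nodes = nodes, n_paths = total),
            class = "metagraph")
}

#' @export
print.metagraph <- function(x, ...) {
  cat(sprintf("<metagraph> %d nodes, %d edges from %d paths; top mediator: residue %d (%d paths)\n",
              nrow(x$nodes), nrow(x$edges), x$n_paths,
              x$nodes$residue[1], x$nodes$participation[1]))
  invisible(x)
}
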