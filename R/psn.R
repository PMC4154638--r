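#' Count inter-residue atom-pair contacts per frame
#'
#' For every residue pair at sequence separation `>= seq_exclusion`, counts
#' the number of distinct atom pairs (one atom from each residue, among the
#' atoms of `selection`) within `cutoff` nm of one another, separately for
#' each frame. Pairs closer in sequence (covalent neighbours and the
#' diagonal) are fixed at zero: network edges represent non-covalent
#' interactions.
#'
#' @param ensemble An [ensemble()].
#' @param selection An `atom_selection` (see [select_atoms()]).
#' @param cutoff Distance cutoff in nm (default 0.45).
#' @param seq_exclusion Minimum sequence separation for a countable pair
#'   (default 2, i.e. `|i - j| >= 2`).
#' @return An `interaction_record`: list with `n_ij` (residues x residues x
#'   frames integer array), `cutoff`, `seq_exclusion` and `residue_types`.
#' @export
count_atom_pairs <- function(ensemble, selection, cutoff = 0.45, seq_exclusion = 2) {
  if (!inherits(selection, "atom_selection")) abort_selection("`selection` must be an atom_selection")
  if (length(unlist(selection$indices)) == 0) abort_selection("empty atom selection")
  if (cutoff <= 0) abort_invalid("`cutoff` must be positive")
  nr <- length(selection$indices)
  nf <- n_frames(ensemble)
  atom_idx <- unlist(selection$indices)
  res_of <- rep(seq_len(nr), lengths(selection$indices))
  n_ij <- array(0L, dim = c(nr, nr, nf))
  for (f in seq_len(nf)) {
    xyz <- ensemble$coords[f, atom_idx, , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    d <- as.matrix(stats::dist(xyz))
    hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      ri <- res_of[hit[, 1]]; rj <- res_of[hit[, 2]]
      keep <- abs(ri - rj) >= seq_exclusion
      if (any(keep)) {
        lo <- pmin(ri[keep], rj[keep]); hi <- pmax(ri[keep], rj[keep])
        counts <- tabulate((lo - 1L) * nr + hi, nbins = nr * nr)
        mat <- matrix(counts, nr, nr)  # column-major: [hi, lo]
        n_ij[, , f] <- mat + t(mat)
      }
    }
  }
  structure(
    list(n_ij = n_ij, cutoff = cutoff, seq_exclusion = as.integer(seq_exclusion),
         residue_types = residue_names(ensemble)),
    class = "interaction_record"
  )
}

#' @export
print.interaction_record <- function(x, ...) {
  cat(sprintf("<interaction_record> %d residues, %d frames, cutoff %.2f nm\n",
              dim(x$n_ij)[1], dim(x$n_ij)[3], x$cutoff))
  invisible(x)
}

#' Residue-type normalization table
#'
#' Normalization values scale raw atom-pair counts into comparable
#' interaction strengths: residue types with large side chains make more
#' atomic contacts and carry larger `N`.
#'
#' @param values Named numeric vector (names are three-letter residue types,
#'   values strictly positive).
#' @param provenance Short label recording where the values come from.
#' @return A `normalization_table`.
#' @export
normalization_table <- function(values, provenance = "user") {
  if (is.null(names(values)) || any(values <= 0)) {
    abort_normalization("normalization values must be a named, strictly positive vector")
  }
  structure(list(values = values, provenance = provenance),
            class = "normalization_table")
}

#' Derive normalization values from the ensemble itself
#'
#' For each residue type present, `N` is the maximum over residues of that
#' type of the total contacts the residue makes (row sum of the pair-count
#' matrix, averaged over frames), floored at 1 so that isolated types still
#' normalize. This self-derived table is the default when no externally
#' calibrated table is supplied; it keeps interaction strengths on a
#' comparable percent scale within a single system.
#'
#' @param record An `interaction_record` from [count_atom_pairs()].
#' @return A `normalization_table` with provenance `"self"`.
#' @export
self_normalization <- function(record) {
  if (!inherits(record, "interaction_record")) {
    abort_invalid("`record` must be an interaction_record")
  }
  mean_n <- apply(record$n_ij, c(1, 2), mean)
  totals <- rowSums(mean_n)
  types <- record$residue_types
  values <- vapply(unique(types), function(tp) {
    max(1, max(totals[types == tp]))
  }, numeric(1))
  names(values) <- unique(types)
  normalization_table(values, provenance = "self")
}

#' Interaction strength from atom-pair counts
#'
#' Converts pair counts into percent-scaled interaction strengths
#' `I_ij = 100 * n_ij / sqrt(N_i * N_j)`, where `N_i`, `N_j` are the
#' normalization values of the two residue types. The factor of 100 puts
#' cutoff scans on the conventional 0-40 scale; set `percent = FALSE` for
#' the bare ratio.
#'
#' @param record An `interaction_record`, or a plain symmetric integer
#'   matrix of counts.
#' @param table A [normalization_table()]; when `record` is an
#'   `interaction_record` and `table` is `NULL`, [self_normalization()] is
#'   used.
#' @param residue_types Required when `record` is a plain matrix: character
#'   vector of residue types, one per row.
#' @param percent Multiply by 100 (default `TRUE`).
#' @return For a record input: the record with added fields `I_ij`
#'   (residues x residues x frames) and `I_mean`. For a matrix input: the
#'   strength matrix.
#' @export
interaction_strength <- function(record, table = NULL, residue_types = NULL,
                                 percent = TRUE) {
  scale <- if (percent) 100 else 1
  if (inherits(record, "interaction_record")) {
    if (is.null(table)) table <- self_normalization(record)
    denom <- strength_denominator(record$residue_types, table)
    nf <- dim(record$n_ij)[3]
    I_ij <- array(0, dim = dim(record$n_ij))
    for (f in seq_len(nf)) I_ij[, , f] <- scale * record$n_ij[, , f] / denom
    record$I_ij <- I_ij
    record$I_mean <- apply(I_ij, c(1, 2), mean)
    record$normalization <- table
    return(record)
  }
  if (is.null(residue_types)) abort_invalid("`residue_types` required for matrix input")
  if (is.null(table)) abort_normalization("a normalization table is required for matrix input")
  denom <- strength_denominator(residue_types, table)
  scale * record / denom
}

strength_denominator <- function(types, table) {
  missing <- setdiff(unique(types), names(table$values))
  if (length(missing) > 0) {
    abort_normalization(paste0("normalization table lacks residue type(s): ",
                               paste(missing, collapse = ", ")))
  }
  n <- table$values[types]
  denom <- sqrt(outer(n, n))
  dimnames(denom) <- NULL
  denom
}

#' Build a protein structure network at a given strength cutoff
#'
#' Nodes are residues; an edge joins residues `i`, `j` whenever
#' `I_ij > i_min` (strict). Connected components of the non-orphan nodes
#' form the clusters; nodes with no edge are orphans. The input matrix is
#' assumed to have zeros wherever pairs are excluded (diagonal, sequence
#' neighbours), as produced by [count_atom_pairs()].
#'
#' @param I_ij Symmetric strength matrix.
#' @param i_min Strength cutoff.
#' @param labels Optional residue labels (defaults to row indices).
#' @return A `psn` object: adjacency and weight matrices, edge tibble,
#'   cluster membership, degrees.
#' @export
build_psn <- function(I_ij, i_min, labels = NULL) {
  I_ij <- as.matrix(I_ij)
  if (nrow(I_ij) != ncol(I_ij) || max(abs(I_ij - t(I_ij))) > 1e-9) {
    abort_invalid("`I_ij` must be a symmetric square matrix")
  }
  nr <- nrow(I_ij)
  if (is.null(labels)) labels <- as.character(seq_len(nr))
  adj <- I_ij > i_min
  diag(adj) <- FALSE
  degrees <- rowSums(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  membership <- comp$membership
  membership[degrees == 0] <- NA_integer_  # orphans belong to no cluster
  # renumber clusters by decreasing size for stable reporting
  sizes <- table(membership)
  if (length(sizes) > 0) {
    ord <- order(-as.integer(sizes), as.integer(names(sizes)))
    remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
    membership <- unname(remap[as.character(membership)])
  }
  ut <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- tibble::tibble(
    i = unname(ut[, 1]), j = unname(ut[, 2]),
    weight = unname(I_ij[ut])
  )
  structure(
    list(adjacency = adj, weights = I_ij, i_min = i_min, labels = labels,
         edges = edges, clusters = membership, degrees = degrees),
    class = "psn"
  )
}

#' @export
print.psn <- function(x, ...) {
  cat(sprintf("<psn> %d nodes, %d edges, %d orphans, largest cluster %d (i_min = %g)\n",
              length(x$degrees), nrow(x$edges), sum(x$degrees == 0),
              largest_cluster_size(x), x$i_min))
  invisible(x)
}

#' Size of the largest cluster of a network
#'
#' Defined as 0 for an edgeless graph (every node an orphan), so that
#' cutoff-scan profiles terminate at zero.
#'
#' @param psn A `psn` object.
#' @return Integer cluster size.
#' @export
largest_cluster_size <- function(psn) {
  if (all(is.na(psn$clusters))) return(0L)
  max(tabulate(psn$clusters))
}

#' Scan the strength cutoff and track the largest cluster
#'
#' Recomputes the network at each cutoff on a regular grid and records the
#' size of the largest connected cluster. Because raising the cutoff only
#' removes edges, the profile is non-increasing.
#'
#' @param I_ij Symmetric strength matrix.
#' @param range Scan range, default `c(0, 40)`.
#' @param step Scan step, default 0.2.
#' @return An `imin_scan`: tibble with columns `i_min` and
#'   `largest_cluster`, with the grid recorded in attributes.
#' @export
imin_scan <- function(I_ij, range = c(0, 40), step = 0.2) {
  if (step <= 0) abort_invalid("`step` must be positive")
  grid <- seq(range[1], range[2], by = step)
  sizes <- vapply(grid, function(im) largest_cluster_size(build_psn(I_ij, im)),
                  integer(1))
  out <- tibble::tibble(i_min = grid, largest_cluster = sizes)
  class(out) <- c("imin_scan", class(out))
  attr(out, "range") <- range
  attr(out, "step") <- step
  out
}

#' Detect the critical strength cutoff from a scan profile
#'
#' The critical cutoff is the scan value at the main transition in the size
#' of the largest cluster. The default rule takes the single largest
#' one-step drop and returns the cutoff on the lower (post-drop) side of
#' that step, with ties broken toward the smaller cutoff; `"smoothed"`
#' averages successive drops over a 3-point moving window before locating
#' the maximum, which is less sensitive to a drop split across two grid
#' points.
#'
#' @param profile An `imin_scan`.
#' @param method `"max-drop"` (default) or `"smoothed"`.
#' @return List with `i_crit` (the cutoff value) and `drop` (cluster-size
#'   decrease at the transition), class `icrit`.
#' @export
detect_icrit <- function(profile, method = c("max-drop", "smoothed")) {
  method <- match.arg(method)
  if (nrow(profile) < 3) abort_invalid("scan profile needs at least 3 points")
  sizes <- profile$largest_cluster
  drops <- -diff(sizes)
  if (all(drops == 0)) {
    abort_no_transition("largest-cluster profile is flat: no transition to detect")
  }
  if (method == "max-drop") {
    k <- which.max(drops)  # first maximum = smaller i_min on ties
    res <- list(i_crit = profile$i_min[k + 1L], drop = drops[k])
  } else {
    sm <- stats::filter(drops, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- 0
    k <- which.max(sm)
    res <- list(i_crit = profile$i_min[k + 1L], drop = drops[k])
  }
  structure(res, class = "icrit")
}

#' @export
print.icrit <- function(x, ...) {
  cat(sprintf("<icrit> i_crit = %g (largest-cluster drop: %d)\n", x$i_crit, x$drop))
  invisible(x)
}

#' Per-node degrees of a network
#'
#' @param psn A `psn` object.
#' @return Tibble with `residue`, `label` and `degree` for every node.
#' @export
node_degrees <- function(psn) {
  tibble::tibble(
    residue = seq_along(psn$degrees),
    label = psn$labels,
    degree = as.integer(psn$degrees)
  )
}

#' Hub residues of a network
#'
#' Hubs are the highly connected nodes of the network. The default
#' threshold (degree at least 4) follows the convention of calling a node a
#' hub when it is involved in more than three edges; the stricter
#' more-than-four-edges variant is obtained with `min_degree = 5`.
#'
#' @param psn A `psn` object.
#' @param min_degree Minimum degree to qualify as a hub (default 4).
#' @return Tibble of hubs (`residue`, `label`, `degree`), sorted by degree
#'   descending then residue index; the full degree profile is attached as
#'   attribute `"degrees"`.
#' @export
hubs <- function(psn, min_degree = 4) {
  prof <- node_degrees(psn)
  out <- dplyr::arrange(
    dplyr::filter(prof, .data$degree >= min_degree),
    dplyr::desc(.data$degree), .data$residue
  )
  attr(out, "degrees") <- prof
  out
}

#' Consensus network over frames
#'
#' Computes, for every residue pair, the fraction of frames in which the
#' pair's interaction strength exceeds `i_min` (its persistence), and keeps
#' an edge when that fraction is at least `persistence_threshold`. Edge
#' weights of the consensus network are the mean strengths over all frames.
#'
#' @param record An `interaction_record` with strengths (see
#'   [interaction_strength()]), or a residues x residues x frames strength
#'   array.
#' @param i_min Strength cutoff applied per frame.
#' @param persistence_threshold Minimum fraction of frames (default 0.5).
#' @param labels Optional residue labels.
#' @return A `psn` with extra fields `persistence` (full matrix of
#'   fractions) and a `persistence` column in the edge tibble.
#' @export
consensus_psn <- function(record, i_min, persistence_threshold = 0.5, labels = NULL) {
  if (inherits(record, "interaction_record")) {
    if (is.null(record$I_ij)) abort_invalid("record has no strengths; run interaction_strength() first")
    arr <- record$I_ij
    if (is.null(labels)) labels <- record$residue_types
  } else {
    arr <- record
  }
  if (length(dim(arr)) != 3) abort_invalid("need a residues x residues x frames array")
  nf <- dim(arr)[3]
  if (nf < 2) abort_invalid("consensus requires at least 2 frames")
  persistence <- apply(arr > i_min, c(1, 2), mean)
  mean_I <- apply(arr, c(1, 2), mean)
  keep <- persistence >= persistence_threshold
  consensus_weights <- mean_I * keep
  # build with a -Inf-style cutoff trick: edges exactly where keep is TRUE
  psn <- build_psn(ifelse(keep, pmax(consensus_weights, i_min * 1.000001, 1e-9), 0),
                   i_min = 0, labels = labels)
  psn$weights <- mean_I
  psn$i_min <- i_min
  psn$persistence_threshold <- persistence_threshold
  psn$persistence <- persistence
  if (nrow(psn$edges) > 0) {
    psn$edges$weight <- mean_I[cbind(psn$edges$i, psn$edges$j)]
    psn$edges$persistence <- persistence[cbind(psn$edges$i, psn$edges$j)]
  } else {
    psn$edges$persistence <- numeric(0)
  }
  psn
}
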