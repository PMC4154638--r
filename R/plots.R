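#' Plot a strength-cutoff scan profile
#'
#' Largest-cluster size versus strength cutoff; the sharp drop locates the
#' critical cutoff.
#'
#' @param object An `imin_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.imin_scan <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$i_min, y = .data$largest_cluster)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(I[min]), y = "largest cluster size") +
    ggplot2::theme_minimal()
}

#' Plot a windowed correlation matrix as a heatmap
#'
#' @param object An `lmi_set`; the window-averaged matrix is shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lmi_set <- function(object, ...) {
  m <- object$average
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$r <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue", y = "residue", fill = "r") +
    ggplot2::theme_minimal()
}

#' Plot the per-residue degree profile of a network
#'
#' Degrees below the hub threshold are shown at zero, mirroring the
#' convention of hub-profile plots.
#'
#' @param object A `psn`.
#' @param min_degree Hub threshold below which degrees are flattened to
#'   zero (default 4); use 1 to show the raw profile.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psn <- function(object, min_degree = 4, ...) {
  df <- node_degrees(object)
  df$degree[df$degree < min_degree] <- 0L
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$degree)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "residue", y = "node degree") +
    ggplot2::theme_minimal()
}

#' Plot meta-graph mediator participation
#'
#' Ranks residues by the number of retained communication paths they
#' appear in.
#'
#' @param object A `metagraph`.
#' @param top Show at most this many residues (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagraph <- function(object, top = 20, ...) {
  df <- utils::head(object$nodes, top)
  df$residue <- factor(df$residue, levels = rev(df$residue))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$participation, y = .data$residue)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "paths containing residue", y = "residue") +
    ggplot2::theme_minimal()
}
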