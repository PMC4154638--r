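#' Linear mutual information over non-overlapping frame windows
#'
#' Splits the ensemble into consecutive non-overlapping windows of
#' `window_frames` frames (trailing frames that do not fill a window are
#' dropped). Within each window the C-alpha coordinates of every frame are
#' least-squares superposed onto the window-mean structure to remove
#' rigid-body motion, and the Gaussian (linear) mutual information between
#' the 3-D displacement vectors of every residue pair is computed from the
#' 3x3 and 6x6 displacement covariance blocks,
#' `MI = (ln det C_i + ln det C_j - ln det C_ij) / 2`,
#' then mapped to the generalized correlation coefficient
#' \code{r = sqrt(1 - exp(-2 MI / 3))}, which lies in `[0, 1]` (0: uncorrelated,
#' 1: fully correlated) and does not depend on the relative orientation of
#' the two residues' fluctuations. Covariance diagonals are regularized by
#' `1e-8` nm^2 so that planted rigid blocks do not produce singular
#' determinants.
#'
#' @param ensemble An [ensemble()].
#' @param window_frames Frames per window (at least 10; default: the
#'   ensemble's `frames_per_window`).
#' @param superpose Reference for the rigid-body fit: `"window-mean"`
#'   (default), `"first-frame"`, or `"none"`.
#' @return An `lmi_set`: list with `windows` (list of correlation matrices),
#'   `average` (element-wise mean over windows), `window_frames`,
#'   `n_windows`.
#' @export
lmi_windows <- function(ensemble, window_frames = NULL,
                        superpose = c("window-mean", "first-frame", "none")) {
  superpose <- match.arg(superpose)
  if (is.null(window_frames)) window_frames <- ensemble$frames_per_window
  window_frames <- as.integer(window_frames)
  if (window_frames < 10) abort_invalid("`window_frames` must be at least 10")
  nf <- n_frames(ensemble)
  if (nf < window_frames) abort_invalid("ensemble has fewer frames than one window")
  sel <- select_atoms(ensemble, "calpha")
  ca_idx <- unlist(sel$indices)
  nr <- length(ca_idx)
  n_windows <- nf %/% window_frames
  windows <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    frames <- ((w - 1L) * window_frames + 1L):(w * window_frames)
    X <- ensemble$coords[frames, ca_idx, , drop = FALSE]
    windows[[w]] <- lmi_matrix(X, superpose)
    attr(windows[[w]], "window") <- w
    attr(windows[[w]], "n_frames") <- window_frames
  }
  average <- Reduce(`+`, windows) / n_windows
  attr(average, "window") <- "average"
  attr(average, "n_frames") <- n_windows * window_frames
  structure(
    list(windows = windows, average = average,
         window_frames = window_frames, n_windows = n_windows),
    class = "lmi_set"
  )
}

#' @export
print.lmi_set <- function(x, ...) {
  cat(sprintf("<lmi_set> %d windows of %d frames, %d residues\n",
              x$n_windows, x$window_frames, nrow(x$average)))
  invisible(x)
}

# generalized correlation matrix from one window of Calpha coordinates
# X: frames x residues x 3
lmi_matrix <- function(X, superpose = "window-mean", reg = 1e-8) {
  nf <- dim(X)[1]; nr <- dim(X)[2]
  flat <- function(A) matrix(A, nrow = dim(A)[1])  # frames x (residues*3), axis-major blocks
  if (superpose != "none") {
    ref <- if (superpose == "first-frame") {
      X[1, , , drop = TRUE]
    } else {
      apply(X, c(2, 3), mean)
    }
    for (pass in 1:2) {
      for (f in seq_len(nf)) {
        X[f, , ] <- kabsch_fit(X[f, , , drop = TRUE], ref)
      }
      if (superpose == "first-frame" && pass == 1) break
      ref <- apply(X, c(2, 3), mean)
    }
  }
  mean_xyz <- apply(X, c(2, 3), mean)
  # displacement matrix: frames x (3 * residues), residue-major
  D <- matrix(NA_real_, nf, 3L * nr)
  for (r in seq_len(nr)) {
    D[, (r - 1L) * 3L + 1:3] <- sweep(X[, r, , drop = TRUE], 2, mean_xyz[r, ])
  }
  C <- stats::cov(D)
  diag(C) <- diag(C) + reg
  logdet3 <- numeric(nr)
  for (r in seq_len(nr)) {
    idx <- (r - 1L) * 3L + 1:3
    logdet3[r] <- determinant(C[idx, idx], logarithm = TRUE)$modulus
  }
  R <- diag(1, nr)
  singular <- FALSE
  for (i in seq_len(nr - 1L)) {
    ii <- (i - 1L) * 3L + 1:3
    for (j in (i + 1L):nr) {
      jj <- (j - 1L) * 3L + 1:3
      Cij <- C[c(ii, jj), c(ii, jj)]
      ld <- determinant(Cij, logarithm = TRUE)
      if (ld$sign <= 0) { singular <- TRUE; mi <- 0 }
      else mi <- max(0, (logdet3[i] + logdet3[j] - as.numeric(ld$modulus)) / 2)
      r_ij <- sqrt(1 - exp(-2 * mi / 3))
      R[i, j] <- R[j, i] <- min(1, r_ij)
    }
  }
  if (singular) {
    warning("singular displacement covariance encountered; affected pairs set to 0",
            call. = FALSE)
  }
  R
}

#' Threshold a correlation matrix at a significance cutoff
#'
#' Marks residue pairs whose correlation reaches the cutoff (inclusive:
#' a value exactly at the cutoff is significant). The diagonal is always
#' `FALSE`.
#'
#' @param matrix Correlation matrix in `[0, 1]`.
#' @param cutoff Significance cutoff in `(0, 1)`, default 0.5.
#' @return Logical matrix.
#' @export
apply_significance_cutoff <- function(matrix, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) abort_invalid("`cutoff` must lie in (0, 1)")
  out <- matrix >= cutoff
  diag(out) <- FALSE
  out
}

#' Frobenius-norm comparison of two correlation matrices
#'
#' The Frobenius norm of the difference,
#' `F = sqrt(sum_ij (a_ij - b_ij)^2)` over all `m^2` elements of two
#' matrices of order `m`, quantifies how similarly two matrices describe
#' the correlated motions. The maximum absolute element-wise difference and
#' a summary of the difference distribution are reported alongside.
#'
#' @param A,B Correlation matrices of identical order.
#' @return A `matrix_comparison`: list with `frobenius`,
#'   `max_abs_difference` and `difference_summary` (quantiles of the
#'   absolute off-diagonal differences).
#' @export
frobenius_norm <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) abort_invalid("matrices must have the same order")
  d <- A - B
  offdiag <- abs(d[row(d) != col(d)])
  structure(
    list(
      frobenius = sqrt(sum(d^2)),
      max_abs_difference = max(abs(d)),
      difference_summary = stats::quantile(offdiag, c(0, 0.25, 0.5, 0.75, 0.9, 1))
    ),
    class = "matrix_comparison"
  )
}

#' @export
print.matrix_comparison <- function(x, ...) {
  cat(sprintf("<matrix_comparison> Frobenius %.4f, max |diff| %.4f\n",
              x$frobenius, x$max_abs_difference))
  invisible(x)
}

#' Replicate-consistency report for correlation matrices
#'
#' Checks whether independent replicates describe the same correlated
#' motions: all pairwise Frobenius norms among the replicates must be lower
#' than every replicate-versus-control norm, where the control is a
#' correlation matrix from a run in which the native structure (and hence
#' its correlation pattern) is not preserved. When per-replicate half
#' matrices are supplied, the half-versus-half norms provide the
#' within-trajectory baseline for judging the pairwise values.
#'
#' @param matrices List of at least two replicate correlation matrices.
#' @param control Control correlation matrix.
#' @param halves Optional list (one entry per replicate) of two-element
#'   lists holding the matrices of the replicate's two halves.
#' @return A `replicate_consistency` report: tibbles `pairwise`,
#'   `vs_control`, `baseline` (or `NULL`) and the logical `consistent`.
#' @export
replicate_consistency <- function(matrices, control, halves = NULL) {
  if (length(matrices) < 2) abort_invalid("need at least 2 replicate matrices")
  n <- length(matrices)
  pairs <- utils::combn(n, 2)
  pairwise <- tibble::tibble(
    a = pairs[1, ], b = pairs[2, ],
    frobenius = apply(pairs, 2, function(p)
      frobenius_norm(matrices[[p[1]]], matrices[[p[2]]])$frobenius)
  )
  vs_control <- tibble::tibble(
    replicate = seq_len(n),
    frobenius = vapply(matrices, function(m)
      frobenius_norm(m, control)$frobenius, numeric(1))
  )
  baseline <- NULL
  if (!is.null(halves)) {
    baseline <- tibble::tibble(
      replicate = seq_along(halves),
      frobenius = vapply(halves, function(h)
        frobenius_norm(h[[1]], h[[2]])$frobenius, numeric(1))
    )
  }
  structure(
    list(pairwise = pairwise, vs_control = vs_control, baseline = baseline,
         consistent = max(pairwise$frobenius) < min(vs_control$frobenius)),
    class = "replicate_consistency"
  )
}

#' @export
print.replicate_consistency <- function(x, ...) {
  cat(sprintf(
    "<replicate_consistency> %s (pairwise max %.3f %s vs-control min %.3f)\n",
    if (x$consistent) "consistent" else "NOT consistent",
    max(x$pairwise$frobenius), if (x$consistent) "<" else ">=",
    min(x$vs_control$frobenius)))
  invisible(x)
}
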