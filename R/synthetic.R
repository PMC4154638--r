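#' Synthetic conformational ensembles with known ground truth
#'
#' The synthetic generator produces clash-free pseudo-protein ensembles whose
#' correlation structure and contact network are known exactly, so that every
#' downstream stage (interaction strengths, consensus networks, LMI
#' estimation, communication paths) can be validated against ground truth.
#' It makes no attempt at realistic protein geometry: residues sit on a
#' smooth curve, each carrying a C-alpha and a small cloud of pseudo
#' side-chain heavy atoms.
#'
#' @name synthetic_ensembles
NULL

# heavy side-chain atom counts per residue type, capped at the five generic
# pseudo-atom names used by the generator
SIDECHAIN_COUNTS <- c(
  ALA = 1L, ARG = 5L, ASN = 4L, ASP = 4L, CYS = 2L, GLN = 5L, GLU = 5L,
  GLY = 0L, HIS = 5L, ILE = 4L, LEU = 4L, LYS = 5L, MET = 4L, PHE = 5L,
  PRO = 3L, SER = 2L, THR = 3L, TRP = 5L, TYR = 5L, VAL = 3L
)
SIDECHAIN_NAMES <- c("CB", "CG", "CD", "CE", "CZ")

# deterministic unit offsets for pseudo side-chain atoms around the centroid
SIDECHAIN_OFFSETS <- rbind(
  c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1)
) * 0.12

#' Build a single-frame reference pseudo-polymer
#'
#' Places `n_residues` residues along a smooth gently-curved line with a
#' C-alpha spacing of 1.0 nm, each residue carrying the number of pseudo
#' side-chain heavy atoms of its (seeded, randomly drawn) amino-acid type
#' (capped at five; glycine gets none and is represented by its C-alpha in
#' side-chain selections). The generous spacing guarantees that residues at
#' sequence separation of two or more start far outside any contact cutoff,
#' so the only contacts present are the ones later planted deliberately.
#'
#' @param n_residues Number of residues (at least 5).
#' @param seed Integer seed controlling residue-type assignment.
#' @param types Optional explicit character vector of three-letter residue
#'   types (length `n_residues`), overriding the seeded random assignment.
#' @return A single-frame [ensemble()].
#' @export
make_reference_polymer <- function(n_residues, seed = 0, types = NULL) {
  if (!is.numeric(n_residues) || n_residues < 5) {
    abort_invalid("`n_residues` must be at least 5")
  }
  n_residues <- as.integer(n_residues)
  if (is.null(types)) {
    types <- with_seed(seed, sample(names(SIDECHAIN_COUNTS), n_residues, replace = TRUE))
  }
  if (length(types) != n_residues || !all(types %in% names(SIDECHAIN_COUNTS))) {
    abort_invalid("`types` must be standard three-letter residue names, one per residue")
  }

  rows <- list()
  coords <- list()
  for (r in seq_len(n_residues)) {
    # smooth curve: 1.0 nm steps along x with a gentle transverse wave
    ca <- c(1.0 * r, 0.25 * sin(r / 3), 0.25 * cos(r / 5))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      residue = r, resno = r, resid = types[r], atom = "CA",
      element = "C", hydrogen = FALSE)
    coords[[length(coords) + 1L]] <- ca
    nsc <- SIDECHAIN_COUNTS[[types[r]]]
    if (nsc > 0) {
      theta <- 2.399963 * r  # golden angle: vary side-chain direction
      centroid <- ca + 0.25 * c(0, cos(theta), sin(theta))
      for (k in seq_len(nsc)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          residue = r, resno = r, resid = types[r],
          atom = SIDECHAIN_NAMES[k], element = "C", hydrogen = FALSE)
        coords[[length(coords) + 1L]] <- centroid + SIDECHAIN_OFFSETS[k, ]
      }
    }
  }
  atoms <- dplyr::bind_rows(rows)
  xyz <- do.call(rbind, coords)
  arr <- array(NA_real_, dim = c(1L, nrow(atoms), 3L))
  arr[1, , ] <- xyz
  ensemble(arr, atoms, frames_per_window = 1L)
}

#' Specify a block covariance structure for residue displacements
#'
#' Residues within a block move with a per-axis Pearson correlation `rho`;
#' residues in different blocks (or in no block) move independently. This is
#' the ground truth against which the LMI estimator is validated: for
#' isotropic equal-variance displacements, the generalized correlation
#' coefficient between two residues equals the absolute per-axis correlation.
#'
#' @param n_residues Residue count the spec applies to.
#' @param blocks List of `list(residues = <indices>, rho = <value in [0,1)>)`.
#'   Residue sets must be disjoint.
#' @param baseline_variance Per-axis displacement variance in nm^2.
#' @return A `covariance_spec` object.
#' @export
covariance_spec <- function(n_residues, blocks = list(), baseline_variance = 0.0025) {
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 1) abort_invalid("`n_residues` must be positive")
  if (!is.numeric(baseline_variance) || baseline_variance <= 0) {
    abort_invalid("`baseline_variance` must be positive")
  }
  seen <- integer(0)
  for (b in blocks) {
    if (is.null(b$residues) || is.null(b$rho)) {
      abort_invalid("each block needs `residues` and `rho`")
    }
    if (b$rho < 0 || b$rho >= 1) abort_invalid("block `rho` must lie in [0, 1)")
    if (any(b$residues < 1 | b$residues > n_residues)) {
      abort_invalid("block residues out of range")
    }
    if (any(b$residues %in% seen)) abort_invalid("block residue sets must be disjoint")
    seen <- c(seen, b$residues)
  }
  structure(
    list(n_residues = n_residues, blocks = blocks,
         baseline_variance = baseline_variance),
    class = "covariance_spec"
  )
}

# n_residues x n_residues per-axis correlation matrix implied by a spec
correlation_target <- function(spec) {
  C <- diag(spec$n_residues)
  for (b in spec$blocks) {
    idx <- b$residues
    C[idx, idx] <- b$rho
    diag(C)[idx] <- 1
    C[idx, idx][diag(length(idx)) == 1] <- 1
  }
  diag(C) <- 1
  C
}

#' Sample a Gaussian ensemble around a reference structure
#'
#' Draws per-frame, per-residue displacement vectors from a multivariate
#' normal whose per-axis correlation between residues follows `spec`
#' (block-constant, zero across blocks; the three axes are independent).
#' All atoms of a residue are displaced rigidly with their residue, so the
#' internal side-chain geometry of the reference is preserved exactly.
#'
#' @param reference Single-frame [ensemble()] (e.g. [make_reference_polymer()]).
#' @param spec A [covariance_spec()] matching the reference residue count.
#' @param n_frames Number of frames to draw (at least 2).
#' @param seed Integer seed.
#' @param frames_per_window Frames per averaging window recorded on the
#'   result; defaults to one twentieth of `n_frames` (at least 10 frames),
#'   mimicking the convention of splitting a trajectory into twenty
#'   fixed-length windows.
#' @return An [ensemble()] with `n_frames` frames.
#' @export
sample_gaussian_ensemble <- function(reference, spec, n_frames, seed = 0,
                                     frames_per_window = NULL) {
  if (!inherits(spec, "covariance_spec")) abort_invalid("`spec` must be a covariance_spec")
  nr <- n_residues(reference)
  if (spec$n_residues != nr) {
    abort_invalid(sprintf("spec is for %d residues but reference has %d",
                          spec$n_residues, nr))
  }
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2) abort_invalid("`n_frames` must be at least 2")
  if (is.null(frames_per_window)) {
    frames_per_window <- max(10L, n_frames %/% 20L)
  }
  C <- correlation_target(spec)
  U <- chol(C)
  sd <- sqrt(spec$baseline_variance)
  disp <- with_seed(seed, {
    lapply(1:3, function(axis) (matrix(stats::rnorm(n_frames * nr), n_frames, nr) %*% U) * sd)
  })
  ref <- reference$coords[1, , , drop = TRUE]
  res_of_atom <- reference$atoms$residue
  coords <- array(NA_real_, dim = c(n_frames, nrow(reference$atoms), 3L))
  for (axis in 1:3) {
    # rigid displacement: every atom inherits its residue's displacement
    coords[, , axis] <- matrix(ref[, axis], n_frames, length(res_of_atom), byrow = TRUE) +
      disp[[axis]][, res_of_atom, drop = FALSE]
  }
  out <- ensemble(coords, reference$atoms, frames_per_window = frames_per_window)
  attr(out, "covariance_spec") <- spec
  out
}

#' Describe a chain of contacts to plant into an ensemble
#'
#' @param residues Ordered residue indices; consecutive entries must be at
#'   sequence separation of at least 2 (contacts are non-covalent).
#' @param min_atom_pairs Minimum number of distinct side-chain atom pairs to
#'   place within the contact cutoff for each consecutive residue pair.
#' @param persistence Fraction of frames (in `[0, 1]`) in which the contacts
#'   are present.
#' @param rng_seed Seed selecting which frames carry the contacts.
#' @return A `planted_chain` object.
#' @export
planted_chain <- function(residues, min_atom_pairs = 2, persistence = 1, rng_seed = 0) {
  residues <- as.integer(residues)
  if (length(residues) < 2) abort_invalid("a chain needs at least 2 residues")
  if (any(duplicated(residues))) abort_invalid("chain residues must be distinct")
  if (any(abs(diff(residues)) < 2)) {
    abort_invalid("consecutive chain residues must be non-adjacent in sequence (|i - j| >= 2)")
  }
  if (persistence < 0 || persistence > 1) abort_invalid("`persistence` must lie in [0, 1]")
  if (min_atom_pairs < 1) abort_invalid("`min_atom_pairs` must be at least 1")
  structure(
    list(residues = residues, min_atom_pairs = as.integer(min_atom_pairs),
         persistence = persistence, rng_seed = as.integer(rng_seed)),
    class = "planted_chain"
  )
}

#' Plant a persistent chain of side-chain contacts into an ensemble
#'
#' In exactly `ceiling(persistence * n_frames)` frames (chosen by
#' `rng_seed`, the same frame subset for every edge so the whole path
#' co-occurs), the side-chain atoms of each chain residue are relocated
#' onto a dedicated "contact line" placed 2 nm off the polymer: tight atom
#' clusters spaced 0.34 nm apart, so that every atom pair of consecutive
#' chain residues sits within the 0.45 nm contact cutoff while
#' non-consecutive chain residues stay beyond 0.6 nm. Each consecutive pair
#' therefore contributes `n_i * n_j` distinct contact pairs, which must be
#' at least `min_atom_pairs`. In the remaining frames all atoms keep their
#' original positions (verified, and nudged apart in the rare case a
#' displacement fluctuation brings a chain pair under 0.6 nm). Atoms of
#' residues outside the chain are never touched.
#'
#' @param ensemble An [ensemble()].
#' @param chain A [planted_chain()].
#' @return The modified [ensemble()], with the chain recorded in
#'   `attr(, "planted_chains")`.
#' @export
plant_contact_chain <- function(ensemble, chain) {
  if (!inherits(chain, "planted_chain")) abort_invalid("`chain` must be a planted_chain")
  at <- ensemble$atoms
  nr <- n_residues(ensemble)
  if (any(chain$residues < 1 | chain$residues > nr)) {
    abort_invalid("chain references residues outside the ensemble")
  }
  nf <- n_frames(ensemble)
  n_contact <- as.integer(ceiling(chain$persistence * nf))
  contact_frames <- with_seed(chain$rng_seed, sort(sample.int(nf, n_contact)))

  sc_atoms <- lapply(chain$residues, function(r) {
    which(at$residue == r & !(at$atom %in% BACKBONE_ATOMS) & !at$hydrogen)
  })
  if (any(lengths(sc_atoms) == 0)) {
    bad <- chain$residues[lengths(sc_atoms) == 0]
    abort_invalid(sprintf(
      "chain residue(s) %s have no side-chain atoms (glycine cannot anchor a planted contact)",
      paste(bad, collapse = ", ")))
  }
  n_atoms <- lengths(sc_atoms)
  pair_products <- n_atoms[-length(n_atoms)] * n_atoms[-1]
  if (any(pair_products < chain$min_atom_pairs)) {
    abort_invalid(sprintf(
      "chain pair(s) cannot host %d distinct atom pairs (smallest product of side-chain atom counts: %d)",
      chain$min_atom_pairs, min(pair_products)))
  }

  # contact line: parallel to x, 2 nm below the polymer in y; each planted
  # chain gets its own line (z-offset) so multiple chains never collide
  n_prev <- length(attr(ensemble, "planted_chains"))
  xs <- vapply(chain$residues, function(r) {
    ensemble$coords[1, which(at$residue == r & at$atom == "CA")[1], 1]
  }, numeric(1))
  anchor <- c(mean(xs) - 0.17 * length(chain$residues), -2.0, 1.5 * n_prev)
  sites <- lapply(seq_along(chain$residues), function(m) {
    anchor + c(0.34 * (m - 1L), 0, 0)
  })

  out <- ensemble
  in_contact <- seq_len(nf) %in% contact_frames
  for (f in seq_len(nf)) {
    if (in_contact[f]) {
      for (m in seq_along(chain$residues)) {
        idx <- sc_atoms[[m]]
        for (k in seq_along(idx)) {
          # tight cluster: atoms within 0.04 nm of the site
          out$coords[f, idx[k], ] <- sites[[m]] + SIDECHAIN_OFFSETS[k, ] / 3
        }
      }
    } else {
      # original positions; guarantee chain pairs stay beyond 0.6 nm
      for (m in seq_len(length(chain$residues) - 1L)) {
        a <- out$coords[f, sc_atoms[[m]], , drop = FALSE]
        b <- out$coords[f, sc_atoms[[m + 1L]], , drop = FALSE]
        dmin <- min(cross_distances(a[1, , , drop = TRUE], b[1, , , drop = TRUE]))
        if (dmin <= 0.6) {
          ca_a <- colMeans(matrix(a[1, , , drop = TRUE], ncol = 3))
          ca_b <- colMeans(matrix(b[1, , , drop = TRUE], ncol = 3))
          u <- ca_b - ca_a; u <- u / sqrt(sum(u^2))
          push <- (0.61 - dmin) * u
          for (aa in sc_atoms[[m + 1L]]) out$coords[f, aa, ] <- out$coords[f, aa, ] + push
        }
      }
    }
  }
  chains <- c(attr(ensemble, "planted_chains"), list(chain))
  attr(out, "planted_chains") <- chains
  attr(out, "contact_frames") <- contact_frames
  out
}

# pairwise distances between two coordinate sets (rows = atoms)
cross_distances <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b))
}

#' Write the ground truth of a synthetic ensemble as JSON
#'
#' Records the covariance spec and planted chains so that downstream
#' validation can be run from files alone.
#'
#' @param ensemble A synthetic [ensemble()] carrying ground-truth attributes.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ensemble, path) {
  spec <- attr(ensemble, "covariance_spec")
  chains <- attr(ensemble, "planted_chains")
  truth <- list(
    covariance_spec = if (!is.null(spec)) {
      list(n_residues = spec$n_residues,
           baseline_variance = spec$baseline_variance,
           blocks = lapply(spec$blocks, function(b)
             list(residues = b$residues, rho = b$rho)))
    },
    planted_chains = lapply(chains, function(ch)
      list(residues = ch$residues, min_atom_pairs = ch$min_atom_pairs,
           persistence = ch$persistence, rng_seed = ch$rng_seed))
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
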