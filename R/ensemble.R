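#' Conformational ensemble container
#'
#' An `ensemble` holds a conformational ensemble of a single protein chain:
#' a `frames x atoms x 3` coordinate array in nanometres plus a per-atom
#' annotation table. Every frame shares the identical atom roster. Residues
#' are indexed internally by a contiguous 1-based index (`residue`); the
#' author/PDB numbering is kept alongside (`resno`) for reporting.
#'
#' @param coords Numeric array `frames x atoms x 3`, coordinates in nm.
#' @param atoms Data frame with one row per atom and columns `residue`
#'   (contiguous 1-based residue index), `resno` (author numbering),
#'   `resid` (three-letter residue name), `atom` (atom name), `element`
#'   (element symbol) and `hydrogen` (logical flag).
#' @param frames_per_window Number of frames corresponding to one averaging
#'   window for windowed analyses (the stand-in for a fixed physical time
#'   window when frames have no timestep). Defaults to the frame count
#'   (a single window).
#'
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(coords, atoms, frames_per_window = dim(coords)[1]) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort_invalid("`coords` must be a frames x atoms x 3 array")
  }
  atoms <- tibble::as_tibble(atoms)
  required <- c("residue", "resno", "resid", "atom", "element", "hydrogen")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort_invalid(paste0("`atoms` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(atoms) != dim(coords)[2]) {
    abort_invalid("atom table and coordinate array disagree on atom count")
  }
  if (!all(is.finite(coords))) {
    abort_invalid("coordinates must be finite")
  }
  res <- unique(atoms$residue)
  if (!identical(as.integer(res), seq_along(res))) {
    abort_invalid("residue indices must be contiguous starting at 1")
  }
  frames_per_window <- as.integer(frames_per_window)
  if (is.na(frames_per_window) || frames_per_window < 1) {
    abort_invalid("`frames_per_window` must be a positive integer")
  }
  structure(
    list(coords = coords, atoms = atoms,
         frames_per_window = frames_per_window),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf(
    "<ensemble> %d frames, %d atoms, %d residues (frames/window: %d)\n",
    n_frames(x), nrow(x$atoms), n_residues(x), x$frames_per_window
  ))
  invisible(x)
}

#' Ensemble dimensions
#'
#' @param x An [ensemble()].
#' @return Integer count of frames or residues.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname n_frames
#' @export
n_residues <- function(x) length(unique(x$atoms$residue))

#' Residue names of an ensemble, one per residue
#' @param x An [ensemble()].
#' @return Character vector of three-letter residue names.
#' @export
residue_names <- function(x) {
  x$atoms$resid[!duplicated(x$atoms$residue)]
}

# backbone atom names never counted as side chain
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Resolve an atom-selection policy
#'
#' Maps every residue to the atom indices used by downstream analyses.
#' Two policies are supported: `"side-chain-heavy"` selects all heavy
#' (non-hydrogen) atoms outside the backbone set `N, CA, C, O, OXT`, with
#' glycine falling back to its C-alpha so it can still participate in the
#' contact network; `"calpha"` selects exactly the CA atom of each residue.
#'
#' @param ensemble An [ensemble()].
#' @param policy `"side-chain-heavy"` or `"calpha"`.
#' @return An `atom_selection`: list with `policy` and `indices`, a
#'   per-residue list of atom indices into the ensemble's atom table.
#' @export
select_atoms <- function(ensemble, policy = c("side-chain-heavy", "calpha")) {
  policy <- match.arg(policy)
  at <- ensemble$atoms
  res_ids <- sort(unique(at$residue))
  indices <- lapply(res_ids, function(r) {
    rows <- which(at$residue == r)
    if (policy == "calpha") {
      sel <- rows[at$atom[rows] == "CA"]
      if (length(sel) != 1L) {
        abort_selection(sprintf(
          "residue %d (%s) has no unique CA atom", r, at$resid[rows][1]))
      }
      return(sel)
    }
    sel <- rows[!(at$atom[rows] %in% BACKBONE_ATOMS) & !at$hydrogen[rows]]
    if (length(sel) == 0L) {
      # glycine (or any side-chain-less residue) is represented by its CA
      sel <- rows[at$atom[rows] == "CA"]
    }
    if (length(sel) == 0L) {
      abort_selection(sprintf(
        "residue %d (%s) has no selectable atom under policy '%s'",
        r, at$resid[rows][1], policy))
    }
    sel
  })
  structure(list(policy = policy, indices = indices), class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> policy '%s', %d residues, %d atoms\n",
              x$policy, length(x$indices), length(unlist(x$indices))))
  invisible(x)
}

#' Read a conformational ensemble
#'
#' Reads a multi-model PDB file (one MODEL per frame) into an [ensemble()].
#' Coordinates are converted from Angstrom to nm. Hydrogens are retained but
#' flagged so contact counting can skip them. Non-protein chains (nucleic
#' acids, water, ligands) are dropped with a warning: the structure network
#' describes the protein only.
#'
#' @param path Path to the file.
#' @param format Input format; only `"pdb"` (multi-model PDB) is built in.
#' @param frames_per_window Frames per averaging window recorded on the
#'   returned ensemble (default: all frames, i.e. one window).
#' @return An [ensemble()].
#' @export
read_ensemble <- function(path, format = "pdb", frames_per_window = NULL) {
  if (!identical(format, "pdb")) {
    abort_format(sprintf("unsupported ensemble format '%s'", format))
  }
  if (!file.exists(path)) {
    abort_format(sprintf("file not found: %s", path))
  }
  check_model_rosters(path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort_format(paste0("PDB parse failed: ", conditionMessage(e)))
  )
  at <- pdb$atom
  protein <- at$resid %in% bio3d::aa.table$aa3
  if (!any(protein)) abort_format("no protein atoms found")
  if (!all(protein)) {
    warning("dropping ", sum(!protein), " non-protein atoms (DNA/ligand/solvent)",
            call. = FALSE)
  }
  keep <- which(protein)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  if (nf == 0L) abort_format("ensemble has zero frames")
  coords <- array(NA_real_, dim = c(nf, length(keep), 3))
  for (a in seq_along(keep)) {
    cols <- (keep[a] - 1L) * 3L + 1:3
    coords[, a, ] <- xyz[, cols, drop = FALSE] / 10  # Angstrom -> nm
  }
  key <- paste(at$chain[keep], at$resno[keep], at$insert[keep])
  residue <- match(key, unique(key))
  element <- at$elesy[keep]
  no_elem <- is.na(element) | element == ""
  element[no_elem] <- vapply(at$elety[keep][no_elem], guess_element, character(1))
  atoms <- tibble::tibble(
    residue = as.integer(residue),
    resno = as.integer(at$resno[keep]),
    resid = at$resid[keep],
    atom = at$elety[keep],
    element = element,
    hydrogen = element == "H"
  )
  if (is.null(frames_per_window)) frames_per_window <- nf
  ensemble(coords, atoms, frames_per_window)
}

# first alphabetic character of the atom name, PDB convention
guess_element <- function(name) {
  ch <- strsplit(gsub("[^A-Za-z]", "", name), "")[[1]]
  if (length(ch) == 0) return("X")
  # names like "1HB" or "HG12" are hydrogens; otherwise first letter
  toupper(ch[1])
}

# cheap pre-parse: every MODEL must carry the identical atom roster
check_model_rosters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) < 2) return(invisible(TRUE))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    abort_format("unbalanced MODEL/ENDMDL records")
  }
  rosters <- mapply(function(s, e) {
    block <- lines[s:e]
    atom <- block[startsWith(block, "ATOM") | startsWith(block, "HETATM")]
    paste(substr(atom, 13, 27), collapse = "\n")
  }, model_starts, model_ends)
  if (length(unique(rosters)) != 1L) {
    abort_format("atom rosters differ across MODEL records")
  }
  invisible(TRUE)
}

#' Write an ensemble as a multi-model PDB
#'
#' One MODEL per frame; coordinates converted from nm to Angstrom.
#'
#' @param ensemble An [ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  at <- ensemble$atoms
  nf <- n_frames(ensemble)
  na <- nrow(at)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * na)
  for (a in seq_len(na)) {
    xyz[, (a - 1L) * 3L + 1:3] <- ensemble$coords[, a, ] * 10  # nm -> Angstrom
  }
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = at$resno, resid = at$resid, elety = at$atom, elesy = at$element
  )
  invisible(path)
}

#' Apply a rigid transformation to every frame
#'
#' Utility used mainly for invariance checks: rotates (and optionally
#' translates) all atoms of all frames by the same rigid-body transform.
#'
#' @param ensemble An [ensemble()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (nm).
#' @return The transformed [ensemble()].
#' @export
transform_ensemble <- function(ensemble, rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) abort_invalid("`rotation` must be 3x3")
  out <- ensemble
  for (f in seq_len(n_frames(ensemble))) {
    out$coords[f, , ] <- sweep(ensemble$coords[f, , , drop = TRUE] %*% t(rotation),
                               2, translation, "+")
  }
  out
}
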