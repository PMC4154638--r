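# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use different algorithms from the package code.

# breadth-first-search hop distances from every source
bfs_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ])) {
          if (!visited[v]) {
            visited[v] <- TRUE
            D[s, v] <- d
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
    }
  }
  D
}

# union-find connected components (path compression)
uf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# random symmetric adjacency matrix
random_adjacency <- function(n, p = 0.2) {
  adj <- matrix(stats::runif(n * n) < p, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  adj | t(adj)
}

# brute-force distinct atom-pair counter for one frame, straight from the
# definition (double loop over residue pairs and their atoms)
brute_pair_counts <- function(ensemble, selection, frame, cutoff = 0.45,
                              seq_exclusion = 2) {
  nr <- length(selection$indices)
  out <- matrix(0L, nr, nr)
  for (i in seq_len(nr - 1)) {
    for (j in (i + 1):nr) {
      if (abs(i - j) < seq_exclusion) next
      cnt <- 0L
      for (a in selection$indices[[i]]) {
        for (b in selection$indices[[j]]) {
          d <- sqrt(sum((ensemble$coords[frame, a, ] - ensemble$coords[frame, b, ])^2))
          if (d <= cutoff) cnt <- cnt + 1L
        }
      }
      out[i, j] <- out[j, i] <- cnt
    }
  }
  out
}

# hand-built ensemble from an explicit coordinate list; one frame unless
# coords is a list of frames. Each residue gets the given atom names.
toy_ensemble <- function(frames, residue_atoms, resid = NULL) {
  if (is.numeric(frames[[1]][[1]])) frames <- list(frames)  # single frame given
  n_res <- length(residue_atoms)
  if (is.null(resid)) resid <- rep("ALA", n_res)
  rows <- list()
  for (r in seq_len(n_res)) {
    for (a in names(residue_atoms[[r]])) {
      rows[[length(rows) + 1]] <- data.frame(
        residue = r, resno = r, resid = resid[r], atom = a,
        element = substr(a, 1, 1), hydrogen = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  nf <- length(frames)
  coords <- array(NA_real_, dim = c(nf, nrow(atoms), 3))
  for (f in seq_len(nf)) {
    k <- 0
    for (r in seq_len(n_res)) {
      for (a in names(residue_atoms[[r]])) {
        k <- k + 1
        coords[f, k, ] <- frames[[f]][[r]][[a]]
      }
    }
  }
  psnpaths::ensemble(coords, atoms, frames_per_window = max(1, nf))
}

# residue types with glycine kept off the given chain (planted contacts
# need side-chain atoms)
fixture_types <- function(n_residues, chain, seed) {
  types <- withr::with_seed(seed, sample(names(psnpaths:::SIDECHAIN_COUNTS),
                                         n_residues, replace = TRUE))
  types[chain][types[chain] == "GLY"] <- "LEU"
  types
}

# standard planted-path fixture: polymer with a persistent contact chain
# whose residues also form a correlated block
planted_fixture <- function(n_residues = 24, chain = c(3, 6, 9, 12, 15),
                            rho = 0.75, persistence = 0.9, n_frames = 200,
                            frames_per_window = 50, seed = 5) {
  ref <- make_reference_polymer(n_residues, seed = seed,
                                types = fixture_types(n_residues, chain, seed))
  spec <- covariance_spec(n_residues,
                          blocks = list(list(residues = chain, rho = rho)))
  ens <- sample_gaussian_ensemble(ref, spec, n_frames = n_frames, seed = seed + 1,
                                  frames_per_window = frames_per_window)
  ch <- planted_chain(chain, min_atom_pairs = 1, persistence = persistence,
                      rng_seed = seed + 2)
  plant_contact_chain(ens, ch)
}

# full PSN machinery from a planted ensemble, shared by path-recovery tests.
# Self-normalized strengths of an otherwise contact-free polymer sit near
# 100, so the cutoff is fixed explicitly instead of scan-detected.
fixture_analysis <- function(ens, i_min = 5, persistence_threshold = 0.5) {
  sel <- select_atoms(ens, "side-chain-heavy")
  rec <- interaction_strength(count_atom_pairs(ens, sel))
  cons <- consensus_psn(rec, i_min = i_min,
                        persistence_threshold = persistence_threshold)
  wf <- ens$frames_per_window
  nw <- n_frames(ens) %/% wf
  wg <- lapply(seq_len(nw), function(w) {
    consensus_psn(rec$I_ij[, , ((w - 1) * wf + 1):(w * wf), drop = FALSE],
                  i_min = i_min,
                  persistence_threshold = persistence_threshold)
  })
  lmi <- lmi_windows(ens, wf)
  list(record = rec, consensus = cons, window_graphs = wg, lmi = lmi)
}
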