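test_that("atom-pair counts match the distance definition", {
  # residue 1: 2 atoms, residue 3: 3 atoms, all mutually within cutoff
  res_atoms <- list(
    list(CA = c(0, 0, 0), CB = c(0.1, 0, 0)),
    list(CA = c(5, 0, 0), CB = c(5.1, 0, 0)),
    list(CA = c(0.2, 0, 0), CB = c(0.2, 0.1, 0), CG = c(0.1, 0.1, 0))
  )
  ens <- toy_ensemble(res_atoms, res_atoms, resid = c("CYS", "CYS", "LEU"))
  sel <- list(policy = "all", indices = list(1:2, 3:4, 5:7))
  class(sel) <- "atom_selection"
  rec <- count_atom_pairs(ens, sel, cutoff = 0.45)
  expect_equal(rec$n_ij[1, 3, 1], 6)    # 2 x 3 atoms, all within cutoff
  expect_equal(rec$n_ij[3, 1, 1], 6)    # symmetry
  expect_equal(rec$n_ij[1, 2, 1], 0)    # far apart
  expect_equal(rec$n_ij[2, 3, 1], 0)    # adjacent in sequence: excluded
  expect_equal(diag(rec$n_ij[, , 1]), rep(0, 3))
})

test_that("counts equal a brute-force oracle on random ensembles", {
  ref <- make_reference_polymer(12, seed = 13)
  ens <- sample_gaussian_ensemble(ref, covariance_spec(12, baseline_variance = 0.09),
                                  4, seed = 5)
  sel <- select_atoms(ens, "side-chain-heavy")
  rec <- count_atom_pairs(ens, sel, cutoff = 1.2)  # wide cutoff: plenty of pairs
  expect_gt(sum(rec$n_ij), 0)
  for (f in 1:4) {
    expect_equal(rec$n_ij[, , f], brute_pair_counts(ens, sel, f, cutoff = 1.2))
  }
})

test_that("contact counting is invariant under global rigid motion", {
  ref <- make_reference_polymer(10, seed = 2,
                                types = fixture_types(10, c(2, 4, 6), 2))
  ens <- sample_gaussian_ensemble(ref, covariance_spec(10), 5, seed = 3)
  ens <- plant_contact_chain(ens, planted_chain(c(2, 4, 6), persistence = 0.8))
  theta <- 0.7
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  ens_rot <- transform_ensemble(ens, rot, translation = c(1, -2, 3))
  sel <- select_atoms(ens, "side-chain-heavy")
  r1 <- count_atom_pairs(ens, sel)
  r2 <- count_atom_pairs(ens_rot, sel)
  expect_equal(r1$n_ij, r2$n_ij)
  expect_equal(interaction_strength(r1)$I_mean, interaction_strength(r2)$I_mean,
               tolerance = 1e-6)
})

test_that("interaction strength follows the normalized percent formula", {
  tab <- normalization_table(c(ALA = 64, LEU = 64))
  m <- matrix(c(0, 4, 4, 0), 2, 2)
  I <- interaction_strength(m, tab, residue_types = c("ALA", "LEU"))
  expect_equal(I[1, 2], 6.25)   # 100 * 4 / sqrt(64 * 64)
  expect_equal(I[2, 1], 6.25)
  expect_equal(interaction_strength(matrix(0, 2, 2), tab,
                                    residue_types = c("ALA", "LEU")),
               matrix(0, 2, 2))
  # doubling all N divides I by 2
  tab2 <- normalization_table(c(ALA = 128, LEU = 128))
  expect_equal(interaction_strength(m, tab2, residue_types = c("ALA", "LEU")),
               I / 2)
  # missing residue type
  expect_error(interaction_strength(m, tab, residue_types = c("ALA", "TRP")),
               class = "psnpaths_normalization_error")
})

test_that("self-normalization takes the per-type maximum of mean total contacts", {
  ref <- make_reference_polymer(12, seed = 13)
  ens <- sample_gaussian_ensemble(ref, covariance_spec(12, baseline_variance = 0.04),
                                  3, seed = 5)
  sel <- select_atoms(ens, "side-chain-heavy")
  rec <- count_atom_pairs(ens, sel, cutoff = 1.5)
  tab <- self_normalization(rec)
  # brute recount
  mean_n <- apply(rec$n_ij, c(1, 2), mean)
  totals <- rowSums(mean_n)
  types <- rec$residue_types
  for (tp in unique(types)) {
    expect_equal(unname(tab$values[tp]), max(1, max(totals[types == tp])))
  }
  expect_true(all(tab$values >= 1))  # floor rule
  expect_identical(tab, self_normalization(rec))  # deterministic
})

test_that("network construction matches hand-built components", {
  I <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(2, 3), c(5, 6))
  for (k in seq_len(nrow(edges))) I[edges[k, 1], edges[k, 2]] <- I[edges[k, 2], edges[k, 1]] <- 10
  g <- build_psn(I, i_min = 5)
  expect_equal(nrow(g$edges), 3)
  expect_equal(largest_cluster_size(g), 3)
  expect_equal(sum(is.na(g$clusters)), 1)           # node 4 is an orphan
  expect_equal(g$clusters[1], g$clusters[2])
  expect_equal(g$clusters[2], g$clusters[3])
  expect_false(isTRUE(g$clusters[1] == g$clusters[5]))
  # strict inequality and edgeless case
  empty <- build_psn(I, i_min = 10)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(largest_cluster_size(empty), 0)
  expect_true(all(is.na(empty$clusters)))
})

test_that("cluster partition equals a union-find oracle on random graphs", {
  withr::local_seed(42)
  for (k in 1:50) {
    n <- sample(4:20, 1)
    adj <- random_adjacency(n, p = 0.15)
    I <- ifelse(adj, 10, 0)
    g <- build_psn(I, i_min = 5)
    oracle <- uf_components(adj)
    # same partition up to relabelling, restricted to non-orphan nodes
    non_orphan <- g$degrees > 0
    if (any(non_orphan)) {
      got <- g$clusters[non_orphan]
      want <- oracle[non_orphan]
      expect_equal(length(unique(got)), length(unique(want)))
      # pairwise co-membership must agree exactly (label-free comparison)
      expect_identical(outer(got, got, "=="), outer(want, want, "=="))
    }
    expect_equal(unname(g$degrees), rowSums(adj))  # degree oracle
  }
})

test_that("cutoff scan is a step function with the expected profile", {
  I <- matrix(10, 5, 5); diag(I) <- 0
  scan <- imin_scan(I, range = c(0, 15), step = 1)
  expect_equal(scan$largest_cluster[scan$i_min < 10], rep(5L, 10))
  expect_equal(scan$largest_cluster[scan$i_min >= 10], rep(0L, 6))
})

test_that("largest cluster is non-increasing along any scan", {
  withr::local_seed(7)
  for (k in 1:10) {
    n <- sample(5:25, 1)
    I <- matrix(runif(n * n, 0, 40), n, n)
    I <- (I + t(I)) / 2; diag(I) <- 0
    scan <- imin_scan(I)
    expect_true(all(diff(scan$largest_cluster) <= 0))
    # profile equals independent recomputation at spot-checked points
    for (p in sample(nrow(scan), 5)) {
      expect_equal(scan$largest_cluster[p],
                   largest_cluster_size(build_psn(I, scan$i_min[p])))
    }
  }
})

test_that("critical cutoff detection finds the main transition", {
  profile <- tibble::tibble(i_min = c(6.6, 6.8, 7.0, 7.2, 7.4),
                            largest_cluster = c(100L, 100L, 100L, 10L, 10L))
  class(profile) <- c("imin_scan", class(profile))
  ic <- detect_icrit(profile)
  expect_equal(ic$i_crit, 7.2)
  expect_equal(ic$drop, 90)
  # two equal drops: smaller cutoff wins
  profile2 <- tibble::tibble(i_min = 1:5, largest_cluster = c(10L, 5L, 5L, 0L, 0L))
  class(profile2) <- c("imin_scan", class(profile2))
  expect_equal(detect_icrit(profile2)$i_crit, 2)
  # flat profile: no transition
  flat <- tibble::tibble(i_min = 1:4, largest_cluster = rep(3L, 4))
  class(flat) <- c("imin_scan", class(flat))
  expect_error(detect_icrit(flat), class = "psnpaths_no_transition")
})

test_that("critical cutoff of a two-scale network separates the scales", {
  # strong intra-block strengths (20), weak inter-block bridges (5)
  n <- 12
  I <- matrix(0, n, n)
  for (b in list(1:4, 5:8, 9:12)) {
    I[b, b] <- 20
  }
  I[4, 5] <- I[5, 4] <- 5
  I[8, 9] <- I[9, 8] <- 5
  diag(I) <- 0
  # scan on a grid that does not alias the planted bridge strength: with the
  # strict edge rule a grid point exactly at 5 would report 5 itself
  ic <- detect_icrit(imin_scan(I, step = 0.3))
  expect_gt(ic$i_crit, 5)
  expect_lt(ic$i_crit, 20)
  expect_equal(ic$drop, 8)  # the bridge transition, not the final collapse
})

test_that("hub detection follows the degree threshold", {
  # star: center 1 with 5 leaves at even offsets (no sequence neighbours)
  I <- matrix(0, 11, 11)
  for (leaf in c(3, 5, 7, 9, 11)) I[1, leaf] <- I[leaf, 1] <- 10
  g <- build_psn(I, i_min = 5)
  h <- hubs(g, min_degree = 4)
  expect_equal(nrow(h), 1)
  expect_equal(h$residue, 1)
  expect_equal(h$degree, 5)
  expect_equal(nrow(hubs(build_psn(matrix(0, 4, 4), 1))), 0)
  prof <- attr(h, "degrees")
  expect_equal(nrow(prof), 11)
  expect_equal(sum(prof$degree), 10)  # handshake: twice the edge count
})

test_that("consensus keeps edges by their frame persistence", {
  nf <- 100
  arr <- array(0, dim = c(4, 4, nf))
  arr[1, 3, 1:60] <- arr[3, 1, 1:60] <- 10   # 60% persistent
  arr[2, 4, 1:49] <- arr[4, 2, 1:49] <- 10   # 49% persistent
  g <- consensus_psn(arr, i_min = 5, persistence_threshold = 0.5)
  expect_equal(nrow(g$edges), 1)
  expect_equal(c(g$edges$i, g$edges$j), c(1, 3))
  expect_equal(g$edges$persistence, 0.6)
  expect_equal(g$persistence[2, 4], 0.49)
  # monotone in the threshold
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    nrow(consensus_psn(arr, 5, th)$edges), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("planted chains pass or fail the persistence filter as constructed", {
  for (pers in c(0.6, 0.4)) {
    ens <- planted_fixture(n_residues = 15, chain = c(3, 6, 9), rho = 0,
                           persistence = pers, n_frames = 100,
                           frames_per_window = 50, seed = 9)
    sel <- select_atoms(ens, "side-chain-heavy")
    rec <- interaction_strength(count_atom_pairs(ens, sel))
    g <- consensus_psn(rec, i_min = 1, persistence_threshold = 0.5)
    edge_present <- g$adjacency[3, 6] && g$adjacency[6, 9]
    if (pers >= 0.5) expect_true(edge_present) else expect_false(edge_present)
  }
})
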