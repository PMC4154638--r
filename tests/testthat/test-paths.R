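line_psn <- function(n) {
  # path graph 1-2-...-n (sequence exclusion irrelevant here: weights given directly)
  I <- matrix(0, n, n)
  for (k in seq_len(n - 1)) I[k, k + 1] <- I[k + 1, k] <- 10
  build_psn(I, i_min = 5)
}

test_that("hop distances and canonical paths are right on a line graph", {
  g <- line_psn(5)
  ap <- all_pairs_shortest_paths(g)
  expect_equal(ap$dist[1, 5], 4)
  expect_equal(shortest_path(ap, 1, 5), 1:5)
  expect_equal(shortest_path(ap, 5, 1), 5:1)
  # disconnected pair
  I <- matrix(0, 4, 4); I[1, 2] <- I[2, 1] <- 10
  ap2 <- all_pairs_shortest_paths(build_psn(I, 5))
  expect_equal(ap2$dist[1, 4], Inf)
  expect_null(shortest_path(ap2, 1, 4))
})

test_that("distances match a BFS oracle exhaustively on small graphs", {
  # every labelled graph on 4 nodes (64 edge subsets) and 5 nodes sampled fully
  for (n in c(4, 5)) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    n_edges <- nrow(pairs)
    for (code in 0:(2^n_edges - 1)) {
      adj <- matrix(FALSE, n, n)
      on <- which(bitwAnd(code, 2^(seq_len(n_edges) - 1)) > 0)
      for (k in on) adj[pairs[k, 1], pairs[k, 2]] <- adj[pairs[k, 2], pairs[k, 1]] <- TRUE
      g <- build_psn(ifelse(adj, 10, 0), 5)
      ap <- all_pairs_shortest_paths(g)
      expect_identical(ap$dist, bfs_distances(adj))
    }
  }
})

test_that("distances match a BFS oracle on random graphs up to 50 nodes", {
  withr::local_seed(33)
  for (k in 1:100) {
    n <- sample(5:50, 1)
    adj <- random_adjacency(n, p = 2 / n)
    ap <- all_pairs_shortest_paths(build_psn(ifelse(adj, 10, 0), 5))
    expect_identical(ap$dist, bfs_distances(adj))
  }
})

test_that("canonical paths are lexicographically smallest among co-shortest", {
  # diamond: 1-2-4 and 1-3-4 both shortest; canonical must go through 2
  I <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(1, 3), c(2, 4), c(3, 4))) {
    I[e[1], e[2]] <- I[e[2], e[1]] <- 10
  }
  ap <- all_pairs_shortest_paths(build_psn(I, 5))
  expect_equal(shortest_path(ap, 1, 4), c(1, 2, 4))
  all_paths <- enumerate_shortest_paths(ap, 1, 4)
  expect_equal(length(all_paths), 2)
  expect_true(all(vapply(all_paths, length, integer(1)) == 3))
})

test_that("adding an edge never increases any pairwise distance", {
  withr::local_seed(8)
  for (k in 1:10) {
    n <- 15
    adj <- random_adjacency(n, p = 0.1)
    d0 <- all_pairs_shortest_paths(build_psn(ifelse(adj, 10, 0), 5))$dist
    free <- which(!adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(free) == 0) next
    pick <- free[sample(nrow(free), 1), ]
    adj[pick[1], pick[2]] <- adj[pick[2], pick[1]] <- TRUE
    d1 <- all_pairs_shortest_paths(build_psn(ifelse(adj, 10, 0), 5))$dist
    expect_true(all(d1 <= d0))
  }
})

test_that("correlation filter requires a correlated intermediate", {
  lmi_all <- matrix(1, 5, 5)
  expect_true(correlation_filter(1:5, lmi_all))
  expect_false(correlation_filter(c(1, 2), lmi_all))  # direct edge: no intermediate
  lmi_none <- diag(5)
  expect_false(correlation_filter(1:5, lmi_none))
  # brute-force oracle on random matrices
  withr::local_seed(14)
  for (k in 1:50) {
    n <- 8
    lmi <- matrix(runif(n * n), n, n); lmi <- (lmi + t(lmi)) / 2; diag(lmi) <- 1
    nodes <- sample(n, sample(3:6, 1))
    inter <- nodes[-c(1, length(nodes))]
    ends <- nodes[c(1, length(nodes))]
    brute <- any(vapply(inter, function(v)
      lmi[v, ends[1]] >= 0.5 || lmi[v, ends[2]] >= 0.5, logical(1)))
    expect_equal(correlation_filter(nodes, lmi), brute)
  }
})

test_that("path occurrence counts windows where every edge is present", {
  g_full <- line_psn(5)
  I_gap <- matrix(0, 5, 5)
  for (k in c(1, 3, 4)) I_gap[k, k + 1] <- I_gap[k + 1, k] <- 10  # edge 2-3 missing
  g_gap <- build_psn(I_gap, 5)
  expect_equal(path_occurrence(1:5, list(g_full, g_full)), 1)
  expect_equal(path_occurrence(1:5, list(g_gap, g_gap)), 0)
  expect_equal(path_occurrence(1:5, list(g_full, g_gap, g_full, g_gap)), 0.5)
  expect_equal(path_occurrence(c(3, 4, 5), list(g_gap)), 1)  # unaffected suffix
})

test_that("target paths apply the node-count and occurrence cascade", {
  g <- line_psn(5)
  lmi <- matrix(1, 5, 5)
  wg <- list(g, g)
  p <- paths_to_targets(g, lmi, wg, targets = 5)
  expect_equal(sort(p$source), c(1, 2))          # 3 and 4 fail length/direct rules
  expect_equal(p$nodes[[which(p$source == 1)]], 1:5)
  expect_equal(p$node_count[p$source == 2], 4)
  direct <- attr(p, "direct_edges")
  expect_equal(direct$source, 4)                  # direct edge reported separately
  # occurrence gate: a window missing an edge kills full-occurrence demands
  I_gap <- matrix(0, 5, 5)
  for (k in c(1, 3, 4)) I_gap[k, k + 1] <- I_gap[k + 1, k] <- 10
  g_gap <- build_psn(I_gap, 5)
  p2 <- paths_to_targets(g, lmi, list(g, g_gap), targets = 5, min_occurrence = 1.0)
  expect_equal(nrow(p2), 0)
  expect_error(paths_to_targets(g, lmi, wg, targets = integer(0)),
               class = "psnpaths_invalid_argument")
})

test_that("retained paths match brute-force enumeration on random instances", {
  withr::local_seed(19)
  for (k in 1:5) {
    n <- 20
    adj <- random_adjacency(n, p = 0.12)
    g <- build_psn(ifelse(adj, 10, 0), 5)
    lmi <- matrix(runif(n * n), n, n); lmi <- (lmi + t(lmi)) / 2; diag(lmi) <- 1
    targets <- sample(n, 2)
    wg <- list(g)
    got <- paths_to_targets(g, lmi, wg, targets = targets, min_occurrence = 0)
    # oracle: igraph shortest paths + manual cascade
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    for (s in setdiff(seq_len(n), targets)) {
      cands <- list()
      for (t in targets) {
        sp <- suppressWarnings(igraph::all_shortest_paths(ig, from = s, to = t))$vpaths
        if (length(sp) == 0) next
        seqs <- lapply(sp, as.integer)
        # lexicographically smallest node sequence (order on vectors, not strings)
        mat <- do.call(rbind, seqs)
        nodes <- seqs[[do.call(order, as.data.frame(mat))[1]]]
        if (length(nodes) < 3) next
        inter <- nodes[-c(1, length(nodes))]
        ok <- any(lmi[inter, c(s, t)] >= 0.5)
        if (!ok || length(nodes) < 4) next
        cands[[length(cands) + 1]] <- nodes
      }
      want <- NULL
      if (length(cands) > 0) {
        lens <- vapply(cands, length, integer(1))
        best <- cands[lens == min(lens)]
        keys <- vapply(best, function(x) x[length(x)], integer(1))
        want <- best[[order(keys)[1]]]
      }
      got_row <- got[got$source == s, ]
      if (is.null(want)) {
        expect_equal(nrow(got_row), 0)
      } else {
        expect_equal(nrow(got_row), 1)
        expect_equal(got_row$node_count, length(want))
        expect_equal(got_row$nodes[[1]][1], s)
      }
    }
  }
})

test_that("long-range classification and histogram conserve path counts", {
  paths <- tibble::tibble(
    source = 1:4, target = 9L,
    nodes = list(1:9, 2:9, c(3, 5, 7, 9), c(4, 6, 9)),
    node_count = c(9L, 8L, 4L, 3L), hop_length = c(8L, 7L, 3L, 2L),
    occurrence = c(1, 0.8, 0.5, 0.3), correlation_ok = TRUE
  )
  cls <- classify_long_range(paths, min_nodes = 8)
  expect_equal(nrow(cls$long_range), 2)
  expect_equal(nrow(cls$shorter), 2)
  expect_equal(sum(cls$histogram$n_paths), nrow(paths))
})

test_that("path-set comparison is exact on node sequences", {
  a <- tibble::tibble(nodes = list(1:4, c(2, 5, 7), c(1, 3, 9)))
  b <- tibble::tibble(nodes = list(1:4, c(9, 3, 1)))
  cmp <- compare_path_sets(a, b)
  expect_equal(nrow(cmp$shared), 1)          # only the exact sequence 1:4
  expect_equal(nrow(cmp$only_a), 2)
  expect_equal(nrow(cmp$only_b), 1)
  expect_equal(cmp$summary$n_a, cmp$summary$n_only_a + cmp$summary$n_shared)
  same <- compare_path_sets(a, a)
  expect_equal(nrow(same$only_a), 0)
  expect_equal(nrow(same$only_b), 0)
  expect_equal(same$summary$relative_change, 0)
  disj <- compare_path_sets(a, tibble::tibble(nodes = list(c(8, 6, 4))))
  expect_equal(nrow(disj$shared), 0)
})

test_that("meta-graph weights are path-sharing probabilities", {
  paths <- tibble::tibble(nodes = list(c(1, 3, 5), c(2, 3, 5), c(2, 4, 6), c(1, 4, 6)))
  mg <- build_metagraph(paths)
  w35 <- mg$edges$weight[mg$edges$i == 3 & mg$edges$j == 5]
  expect_equal(w35, 0.5)                      # edge (3,5) in 2 of 4 paths
  w13 <- mg$edges$weight[mg$edges$i == 1 & mg$edges$j == 3]
  expect_equal(w13, 0.25)
  # double-counting identity: sum over edges of counts = total hop length
  expect_equal(sum(mg$edges$weight) * mg$n_paths,
               sum(vapply(paths$nodes, function(p) length(p) - 1, numeric(1))))
  expect_error(build_metagraph(paths[0, ]), class = "psnpaths_invalid_argument")
})

test_that("a planted chain is recovered as the top path and its mediator is load-bearing", {
  chain <- c(3, 6, 9, 12, 15)
  ens <- planted_fixture(chain = chain, persistence = 0.9, n_frames = 200,
                         frames_per_window = 50)
  an <- fixture_analysis(ens)
  p <- paths_to_targets(an$consensus, an$lmi$average, an$window_graphs,
                        targets = max(chain))
  expect_gt(nrow(p), 0)
  # between its termini the top-occurrence path is exactly the planted chain
  head_row <- which(p$source == chain[1])
  expect_equal(p$nodes[[head_row]], chain)
  expect_equal(p$occurrence[head_row], max(p$occurrence))
  expect_gt(p$occurrence[head_row], 0.5)
  # mediator removal: cutting the central node disconnects the path
  mid <- chain[ceiling(length(chain) / 2)]
  mg <- build_metagraph(p)
  expect_true(mg$nodes$residue[1] %in% chain[-c(1, length(chain))])  # an interior mediator leads
  pruned <- an$consensus
  pruned$adjacency[mid, ] <- pruned$adjacency[, mid] <- FALSE
  ap <- all_pairs_shortest_paths(pruned)
  expect_false(is.finite(ap$dist[chain[1], max(chain)]))
  # degrading persistence below the threshold removes the chain entirely
  ens_low <- planted_fixture(chain = chain, persistence = 0.4, n_frames = 200,
                             frames_per_window = 50)
  sel <- select_atoms(ens_low, "side-chain-heavy")
  rec <- interaction_strength(count_atom_pairs(ens_low, sel))
  cons_low <- consensus_psn(rec, i_min = 1, persistence_threshold = 0.5)
  expect_equal(nrow(cons_low$edges), 0)
})
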