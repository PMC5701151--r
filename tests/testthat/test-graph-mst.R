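test_that("Kruskal picks the greedy tree on small examples", {
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- 0.9; W3[1, 3] <- 0.6; W3[2, 3] <- 0.3
  W3 <- W3 + t(W3)
  tr <- maximum_spanning_tree(W3)
  expect_equal(nrow(tr$edges), 2)
  expect_equal(sort(paste(tr$edges[, 1], tr$edges[, 2])), c("1 2", "1 3"))

  # disconnected input errors with component information
  Wd <- matrix(0, 4, 4)
  Wd[1, 2] <- Wd[2, 1] <- 0.5
  Wd[3, 4] <- Wd[4, 3] <- 0.5
  expect_error(maximum_spanning_tree(Wd), "disconnected")
})

test_that("tree weight is maximal over all spanning trees (exhaustive 7-node oracle)", {
  W <- rand_sym(7, seed = 5)
  tr <- maximum_spanning_tree(W)
  expect_equal(nrow(tr$edges), 6)

  # enumerate all 7^5 = 16807 labelled trees via Pruefer sequences
  seqs <- as.matrix(expand.grid(rep(list(1:7), 5)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_edges(seqs[r, ], 7)
    wsum <- sum(W[ed])
    if (wsum > best) best <- wsum
  }
  expect_equal(tr$total_weight, best)

  # independent library cross-check (igraph minimum tree on negated weights)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  mst_ig <- igraph::mst(g, weights = -igraph::E(g)$weight)
  expect_equal(sum(igraph::E(mst_ig)$weight), tr$total_weight)
})

test_that("MST depends only on weight ranks", {
  W <- rand_sym(10, seed = 6)
  t1 <- maximum_spanning_tree(W)
  t2 <- maximum_spanning_tree(W^3)
  expect_equal(t1$edges, t2$edges)
})

test_that("leaf metrics count degree-1 nodes", {
  star <- spanning_tree_from_edges(13, star_edges(13))
  expect_equal(leaf_metrics(star)$leaf_number, 12)
  expect_equal(leaf_metrics(star)$leaf_fraction, 12 / 13)

  line <- spanning_tree_from_edges(13, line_edges(13))
  expect_equal(leaf_metrics(line)$leaf_number, 2)

  # edge-count denominator variant
  expect_equal(leaf_metrics(star, denominator = "edges")$leaf_fraction, 1)

  for (s in 1:4) {
    ed <- random_tree(9, seed = 40 + s)
    tr <- spanning_tree_from_edges(9, ed)
    deg <- tabulate(c(ed), nbins = 9)
    expect_equal(leaf_metrics(tr)$leaf_number, sum(deg == 1))
  }
})

test_that("tree betweenness matches path enumeration and its star/line limits", {
  star <- spanning_tree_from_edges(8, star_edges(8))
  expect_equal(betweenness_max(star), 1)

  line3 <- spanning_tree_from_edges(3, line_edges(3))
  expect_equal(betweenness_max(line3), 1)  # the middle node carries the only path

  for (s in 1:5) {
    ed <- random_tree(8, seed = 50 + s)
    tr <- spanning_tree_from_edges(8, ed)
    expect_equal(max(oracle_tree_bc(ed, 8)), betweenness_max(tr))
  }
  expect_error(betweenness_max(spanning_tree_from_edges(2, cbind(1, 2))),
               "at least 3")
})

test_that("sum of unnormalized BC equals total interior path length", {
  # Sum over nodes of pairs-through-node = sum over pairs of (path_len - 1)
  for (s in 1:3) {
    n <- 9
    ed <- random_tree(n, seed = 60 + s)
    tr <- spanning_tree_from_edges(n, ed)
    bc_pairs <- oracle_tree_bc(ed, n) * ((n - 1) * (n - 2) / 2)
    g <- igraph::graph_from_edgelist(ed, directed = FALSE)
    L <- igraph::distances(g)
    expect_equal(sum(bc_pairs), sum(L[upper.tri(L)] - 1))
  }
})

test_that("tree hierarchy reproduces the star and line limits and stays in (0, 1]", {
  for (n in c(5, 13, 128)) {
    star <- spanning_tree_from_edges(n, star_edges(n))
    expect_equal(tree_hierarchy(star), 0.5)
  }
  # line: TH = 2 / (2 (N-1) BC_max) shrinks towards 0 with N
  th_line <- sapply(c(5, 15, 45), function(n) {
    tree_hierarchy(spanning_tree_from_edges(n, line_edges(n)))
  })
  expect_true(all(diff(th_line) < 0))
  expect_lt(th_line[3], 0.1)

  # exhaustive range check over all labelled trees on 4-6 nodes
  for (n in 4:6) {
    seqs <- as.matrix(expand.grid(rep(list(1:n), n - 2)))
    for (r in seq_len(nrow(seqs))) {
      tr <- spanning_tree_from_edges(n, prufer_edges(seqs[r, ], n))
      th <- tree_hierarchy(tr)
      expect_gt(th, 0); expect_lte(th, 1)
    }
  }
})

test_that("mst_metrics bundles the tree measures consistently", {
  W <- rand_sym(12, seed = 7)
  m <- mst_metrics(W)
  tr <- maximum_spanning_tree(W)
  expect_equal(m$leaf_number, leaf_metrics(tr)$leaf_number)
  expect_equal(m$leaf_fraction, m$leaf_number / 12)
  expect_equal(m$bc_max, betweenness_max(tr))
  expect_equal(m$tree_hierarchy, tree_hierarchy(tr))
  expect_gte(m$leaf_number, 2); expect_lte(m$leaf_number, 11)
})
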