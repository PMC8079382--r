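test_that("eigenvector centrality matches closed forms", {
  # equal-weight triangle: symmetry forces all scores equal (and max-scaled to 1)
  tri <- tagnet:::graph_from_edges(c("a", "a", "b"), c("b", "c", "c"))
  expect_equal(unname(eigenvector_centrality(tri)$node_scores), rep(1, 3),
               tolerance = 1e-9)

  # star K1,3: center 1, leaves 1/sqrt(3) (bipartite, exercises the shift)
  st <- star_graph()
  sc <- eigenvector_centrality(st)$node_scores
  expect_equal(unname(sc[c("c", "l1", "l2", "l3")]),
               c(1, rep(1 / sqrt(3), 3)), tolerance = 1e-8)

  # k-regular equally weighted connected graph is uniform (cycle C6)
  cyc <- tagnet:::graph_from_edges(sprintf("v%d", 1:6),
                                   sprintf("v%d", c(2:6, 1)))
  expect_equal(unname(eigenvector_centrality(cyc)$node_scores), rep(1, 6),
               tolerance = 1e-8)
})

test_that("eigenvector centrality agrees with a dense eigensolver", {
  for (s in 1:5) {
    g <- random_connected_er(30, 0.2, seed = s, weights = TRUE)
    got <- eigenvector_centrality(g)$node_scores
    want <- oracle_eigenvector(g)
    expect_lt(max(abs(got[names(want)] - want)), 1e-8)
  }
})

test_that("eigenvector output is invariant to the start vector", {
  g <- random_connected_er(25, 0.25, seed = 7, weights = TRUE)
  set.seed(99)
  s1 <- runif(25, 0.1, 2); s2 <- runif(25, 0.1, 2)
  a <- eigenvector_centrality(g, start = s1)$node_scores
  b <- eigenvector_centrality(g, start = s2)$node_scores
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("eigenvector on disconnected graphs scores the giant component", {
  g <- tagnet:::graph_from_edges(c("a", "a", "x"), c("b", "c", "y"))
  expect_warning(sc <- eigenvector_centrality(g)$node_scores, "disconnected")
  expect_equal(unname(sc[c("x", "y")]), c(0, 0))
  expect_equal(max(sc), 1)
  expect_error(suppressWarnings(eigenvector_centrality(
    tagnet:::graph_from_edges("a", "b", -1))), "negative")
})

test_that("betweenness matches hand-enumerated path graphs", {
  p3 <- path_graph(c("a", "b", "c"))
  expect_equal(unname(betweenness_centrality(p3, "unweighted", normalized = FALSE)$node_scores),
               c(0, 1, 0))
  expect_equal(unname(betweenness_centrality(p3, "unweighted")$node_scores),
               c(0, 1, 0))
  p4 <- path_graph(c("a", "b", "c", "d"))
  expect_equal(unname(betweenness_centrality(p4, "unweighted")$node_scores),
               c(0, 2 / 3, 2 / 3, 0))

  # K4: every pair adjacent, all betweenness 0
  k4 <- tagnet:::graph_from_edges(c("a", "a", "a", "b", "b", "c"),
                                  c("b", "c", "d", "c", "d", "d"))
  expect_true(all(betweenness_centrality(k4)$node_scores == 0))

  # inverse-weight mode rejects non-positive weights
  g0 <- tagnet:::graph_from_edges("a", "b", 1)
  g0$edges$weight <- 0
  expect_error(betweenness_centrality(g0), "positive")
})

test_that("edge betweenness matches hand enumeration and bridge bounds", {
  p3 <- path_graph(c("a", "b", "c"))
  eb <- edge_betweenness(p3, "unweighted")$edge_scores
  expect_equal(unname(eb), c(2, 2))

  tc <- two_clique_bridge()
  eb2 <- edge_betweenness(tc, "unweighted")$edge_scores
  expect_equal(unname(eb2[["a1|b1"]]), 9)  # 3x3 cross pairs
  # any disconnecting edge carries at least the product of the side sizes
  expect_gte(eb2[["a1|b1"]], 3 * 3)
})

test_that("betweenness equals the brute-force oracle on random graphs (both modes)", {
  for (s in 1:10) {
    n <- 5 + (s %% 6)
    g <- random_connected_er(n, 0.4, seed = s, weights = TRUE)
    ix <- tagnet:::edge_indices(g)
    for (mode in c("unweighted", "inverse_weight")) {
      len <- if (mode == "inverse_weight") 1 / g$edges$weight else rep(1, nrow(g$edges))
      want <- oracle_betweenness(nrow(g$nodes), ix$i, ix$j, len)
      got_n <- betweenness_centrality(g, mode, normalized = FALSE)$node_scores
      got_e <- edge_betweenness(g, mode)$edge_scores
      expect_equal(unname(got_n), want$node, tolerance = 1e-12)
      expect_equal(unname(got_e), want$edge, tolerance = 1e-12)
    }
  }
})

test_that("all measures are invariant under node relabelling", {
  g <- random_connected_er(15, 0.3, seed = 3, weights = TRUE)
  set.seed(5)
  relab <- setNames(sprintf("z%02d", sample(15)), g$nodes$hashtag)
  g2 <- tagnet:::graph_from_edges(unname(relab[g$edges$from]),
                                  unname(relab[g$edges$to]), g$edges$weight)
  for (fn in list(
    function(x) eigenvector_centrality(x)$node_scores,
    function(x) betweenness_centrality(x)$node_scores,
    function(x) degree_and_strength(x)$strength$node_scores
  )) {
    a <- fn(g); b <- fn(g2)
    expect_equal(unname(a[names(relab)]), unname(b[unname(relab)]),
                 tolerance = 1e-8)
  }
})

test_that("degree and strength match the adjacency-matrix oracle", {
  st <- star_graph()
  ds <- degree_and_strength(st)
  expect_equal(ds$degree$params$raw[["c"]], 3)
  expect_equal(ds$strength$params$raw[["c"]], 3)

  g <- random_connected_er(20, 0.3, seed = 9, weights = TRUE)
  A <- matrix(0, 20, 20, dimnames = list(g$nodes$hashtag, g$nodes$hashtag))
  for (e in seq_len(nrow(g$edges))) {
    A[g$edges$from[e], g$edges$to[e]] <- g$edges$weight[e]
    A[g$edges$to[e], g$edges$from[e]] <- g$edges$weight[e]
  }
  expect_equal(degree_and_strength(g)$strength$params$raw, rowSums(A))

  # isolated node: degree and strength 0
  giso <- build_cooccurrence_graph(corpus_from_sets(list(c("a", "b"), "z")),
                                   c("a", "b", "z"))
  expect_equal(degree_and_strength(giso)$degree$params$raw[["z"]], 0)
})

test_that("disconnected betweenness is normalized per component", {
  # two P3 components: each middle node has raw 1, normalized by (3-1)(3-2)/2 = 1
  g <- tagnet:::graph_from_edges(c("a", "b", "x", "y"), c("b", "c", "y", "z"))
  sc <- betweenness_centrality(g, "unweighted")$node_scores
  expect_equal(unname(sc[c("b", "y")]), c(1, 1))
})
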