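test_that("modularity matches hand computations", {
  tc <- two_clique_bridge()
  one <- setNames(rep(0L, 6), tc$nodes$hashtag)
  expect_equal(modularity_q(tc, one), 0)

  cliques <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L),
                      c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_equal(modularity_q(tc, cliques), 5 / 14)

  tri <- tagnet:::graph_from_edges(c("a", "a", "b"), c("b", "c", "c"))
  singletons <- setNames(0:2, c("a", "b", "c"))
  expect_equal(modularity_q(tri, singletons), -1 / 3)

  expect_error(modularity_q(tc, cliques[-1]), "missing")
})

test_that("fast-greedy recovers the two-clique partition, confirmed optimal by exhaustion", {
  tc <- two_clique_bridge()
  part <- fast_greedy_communities(tc)
  expect_equal(part$n_communities, 2)
  expect_equal(part$modularity, 5 / 14, tolerance = 1e-12)
  expect_equal(unname(part$membership[c("a1", "a2", "a3")]), rep(0L, 3))
  expect_equal(unname(part$membership[c("b1", "b2", "b3")]), rep(1L, 3))

  best <- oracle_best_modularity(tc)
  expect_equal(part$modularity, best$q, tolerance = 1e-12)
  expect_equal(nmi(part$membership[tc$nodes$hashtag],
                   best$membership[tc$nodes$hashtag]), 1)
})

test_that("single edge collapses to one community with Q = 0", {
  g <- tagnet:::graph_from_edges("a", "b", 1)
  part <- fast_greedy_communities(g)
  expect_equal(part$n_communities, 1)
  expect_equal(part$modularity, 0)
})

test_that("partition invariants hold on random graphs", {
  for (s in 1:5) {
    g <- random_connected_er(12, 0.3, seed = s + 20, weights = TRUE)
    part <- fast_greedy_communities(g)
    n <- nrow(g$nodes)
    # connected graph: exactly n-1 recorded merges
    expect_equal(nrow(part$dendrogram), n - 1)
    # community indices contiguous from 0
    expect_setequal(unique(unname(part$membership)),
                    0:(part$n_communities - 1))
    # returned Q equals the independent modularity formula
    expect_equal(part$modularity, modularity_q(g, part$membership),
                 tolerance = 1e-12)
    # greedy beats the trivial partitions
    tags <- g$nodes$hashtag
    expect_gte(part$modularity, modularity_q(g, setNames(rep(0, n), tags)))
    expect_gte(part$modularity,
               modularity_q(g, setNames(seq_len(n), tags)) - 1e-12)
  }
})

test_that("the dendrogram replays to the recorded modularity trace", {
  g <- random_connected_er(10, 0.4, seed = 42, weights = TRUE)
  part <- fast_greedy_communities(g)
  tags <- g$nodes$hashtag
  owner <- setNames(seq_along(tags), tags)
  for (k in seq_len(nrow(part$dendrogram))) {
    a <- part$dendrogram$a[k]; b <- part$dendrogram$b[k]
    owner[owner == owner[[b]]] <- owner[[a]]
    expect_equal(modularity_q(g, owner), part$dendrogram$modularity[k],
                 tolerance = 1e-12)
  }
})

test_that("membership structure is invariant under node reordering", {
  g <- random_connected_er(14, 0.3, seed = 77, weights = TRUE)
  p1 <- fast_greedy_communities(g)
  set.seed(3)
  ord <- sample(nrow(g$edges))
  g2 <- tagnet:::graph_from_edges(g$edges$from[ord], g$edges$to[ord],
                                  g$edges$weight[ord])
  p2 <- fast_greedy_communities(g2)
  expect_equal(nmi(p1$membership[g$nodes$hashtag],
                   p2$membership[g$nodes$hashtag]), 1)
})

test_that("force_k cuts the dendrogram at the requested community count", {
  g <- random_connected_er(12, 0.35, seed = 15, weights = TRUE)
  p3 <- fast_greedy_communities(g, force_k = 3)
  expect_equal(p3$n_communities, 3)
  expect_error(fast_greedy_communities(g, force_k = 40), "not reachable")
})

test_that("planted topics are recovered on a strongly separated corpus", {
  cfg <- generator_config(posts_per_area = 2000, p_topic = 1,
                          bot_fraction = 0, ad_fraction = 0,
                          misspelling_rate = 0, seed = 123)
  corp <- generate_corpus(cfg, 1)
  sel <- select_top_hashtags(hashtag_frequencies(corp), 150, exclude = "area01")
  g <- build_cooccurrence_graph(corp, sel)
  part <- fast_greedy_communities(g)
  truth <- planted_topic(sel)
  keep <- !is.na(truth)
  expect_equal(nmi(part$membership[sel[keep]], truth[keep]), 1)
})

test_that("CES labelling scores communities against the lexicon", {
  lex <- ces_lexicon(list("wildlife appreciation" = c("wildlife", "nature", "penguin")))
  part <- structure(list(membership = setNames(c(0L, 0L, 0L), c("wildlife", "nature", "penguin"))),
                    class = "community_partition")
  lab <- suggest_ces_labels(part, lex)
  expect_equal(lab$label[1], "wildlife appreciation")
  expect_equal(lab$score[1], 1)

  part2 <- structure(list(membership = setNames(c(0L, 0L), c("travel", "photo"))),
                     class = "community_partition")
  lab2 <- suggest_ces_labels(part2, lex)
  expect_equal(lab2$label, "Other")

  # Galapagos-like beach/holiday community under the shipped lexicon:
  # the beach class must outrank the wildlife class
  lex_full <- read_ces_lexicon()
  part3 <- structure(list(membership = setNames(
    rep(0L, 5), c("beach", "sun", "holiday", "swim", "wildlife"))),
    class = "community_partition")
  lab3 <- suggest_ces_labels(part3, lex_full)
  beach <- lab3$score[lab3$label == "Recreational (beach)"]
  wild <- lab3$score[lab3$label == "Nature and wildlife appreciation"]
  expect_gt(beach, wild)
  expect_equal(lab3$label[1], "Recreational (beach)")
})
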