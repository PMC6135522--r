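# The worked sample network: fly X1 touches X2..X6 once each (plus a second
# X1->X2 interaction), and receives touches from X2, X3 and X5.
sample_network <- function() {
  ev <- tibble::tibble(
    interactor_id = c(1, 1, 1, 1, 1, 1, 2, 3, 5),
    interacted_id = c(2, 2, 3, 4, 5, 6, 1, 1, 1)
  )
  build_adjacency(ev, n_flies = 6)
}

test_that("worked-example degrees: out-degree 5 and in-degree 3 for fly X1", {
  net <- sample_network()
  expect_equal(net$counts[1, 2], 2L)
  d <- degrees(net)
  expect_equal(d$out_degree[1], 5)
  expect_equal(d$in_degree[1], 3)
  expect_equal(d$degree, d$in_degree + d$out_degree)
})

test_that("adjacency construction tallies events and rejects bad ids", {
  expect_equal(build_adjacency(tibble::tibble(interactor_id = integer(),
                                              interacted_id = integer()), 4)$counts,
               matrix(0L, 4, 4))
  withr::with_seed(1, {
    ev <- tibble::tibble(interactor_id = sample(1:5, 60, TRUE),
                         interacted_id = sample(1:5, 60, TRUE))
    ev <- ev[ev$interactor_id != ev$interacted_id, ]
    net <- build_adjacency(ev, 5)
    tall <- matrix(0L, 5, 5)
    for (r in seq_len(nrow(ev)))
      tall[ev$interactor_id[r], ev$interacted_id[r]] <-
        tall[ev$interactor_id[r], ev$interacted_id[r]] + 1L
    expect_equal(net$counts, tall)
  })
  expect_error(build_adjacency(tibble::tibble(interactor_id = 1, interacted_id = 1), 4),
               class = "flynet_bad_event")
  expect_error(build_adjacency(tibble::tibble(interactor_id = 9, interacted_id = 1), 4),
               class = "flynet_bad_event")
})

test_that("closed forms on the complete and empty digraphs", {
  n <- 5
  full <- social_network(matrix(1, n, n) - diag(n))
  expect_equal(clustering_coefficient(full), rep(1, n))
  expect_equal(betweenness_centrality(full), rep(0, n))
  g <- global_metrics(full)
  expect_equal(g$density, 1)
  expect_equal(g$transitivity, 1)
  expect_equal(g$global_efficiency, 1)
  expect_true(is.na(g$assortativity))  # zero degree variance: undefined

  zero <- social_network(matrix(0, n, n))
  gz <- global_metrics(zero)
  expect_equal(gz$density, 0)
  expect_equal(gz$weighted_total_interaction, 0)
  expect_equal(gz$global_efficiency, 0)
})

test_that("directed path a->b->c puts betweenness only on b", {
  counts <- matrix(0, 3, 3); counts[1, 2] <- 1; counts[2, 3] <- 1
  b <- betweenness_centrality(social_network(counts))
  expect_equal(b, c(0, 1 / 2, 0))  # one of the two (s,t) pairs runs through b
})

test_that("all nine parameters match definitional loop oracles on random digraphs", {
  withr::with_seed(42, {
    for (rep in 1:30) {
      counts <- random_counts(6)
      net <- social_network(counts)
      d <- degrees(net)
      o <- oracle_degrees(counts)
      expect_equal(d$in_degree, unname(o[, "in"]))
      expect_equal(d$out_degree, unname(o[, "out"]))
      expect_equal(d$weighted_in_degree, unname(o[, "win"]), tolerance = 1e-10)
      expect_equal(d$weighted_out_degree, unname(o[, "wout"]), tolerance = 1e-10)
      expect_equal(clustering_coefficient(net), oracle_clustering(net$weights),
                   tolerance = 1e-10)
      expect_equal(betweenness_centrality(net), oracle_betweenness(net$weights),
                   tolerance = 1e-10)
      g <- global_metrics(net)
      expect_equal(g$global_efficiency, oracle_global_efficiency(net$weights),
                   tolerance = 1e-10)
      expect_equal(g$transitivity, oracle_transitivity(counts), tolerance = 1e-10)
      expect_equal(g$assortativity, oracle_assortativity(counts), tolerance = 1e-10)
      expect_equal(g$density, sum(counts > 0) / (6 * 5))
      expect_equal(g$weighted_total_interaction, sum(net$weights))
    }
  })
})

test_that("per-node parameters are permutation-equivariant, global ones invariant", {
  withr::with_seed(3, {
    counts <- random_counts(7)
    net <- social_network(counts)
    p <- sample(7)
    netp <- social_network(counts[p, p])
    expect_equal(clustering_coefficient(netp), clustering_coefficient(net)[p],
                 tolerance = 1e-12)
    expect_equal(betweenness_centrality(netp), betweenness_centrality(net)[p],
                 tolerance = 1e-12)
    expect_equal(degrees(netp)$weighted_degree, degrees(net)$weighted_degree[p],
                 tolerance = 1e-12)
    g1 <- global_metrics(net); g2 <- global_metrics(netp)
    expect_equal(g1, g2, tolerance = 1e-12)
  })
})

test_that("relabelling by outgoing activity sorts ascending and preserves the multiset", {
  net <- sample_network()
  rl <- relabel_by_outgoing(net)
  s <- rowSums(rl$net$weights)
  expect_true(all(diff(s) >= -1e-12))
  expect_equal(sort(as.vector(rl$net$counts)), sort(as.vector(net$counts)))
  # already-sorted network returns the identity permutation
  rl2 <- relabel_by_outgoing(rl$net)
  expect_equal(rl2$perm, seq_len(net$n))
  # parameters unchanged as a multiset
  expect_equal(sort(clustering_coefficient(rl$net)),
               sort(clustering_coefficient(net)), tolerance = 1e-12)
})

test_that("tidy and glance return well-formed tibbles", {
  net <- sample_network()
  td <- tidy(net)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$count), sum(net$counts))
  expect_equal(nrow(glance(net)), 1)
  p <- network_params(net)
  expect_equal(nrow(p$nodes), 6)
  expect_named(p$nodes, c("fly_id", "in_degree", "out_degree", "degree",
                          "weighted_in_degree", "weighted_out_degree",
                          "weighted_degree", "clustering_coefficient",
                          "betweenness_centrality"))
})
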