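# bipartite network construction, centrality, topology, scale-free fit

toy_edges <- function() {
  data.frame(
    compound_id = c("c1", "c1", "c2"),
    target_id = c("t1", "t2", "t2"),
    score = c(9.5, 10, 8.5),
    stringsAsFactors = FALSE
  )
}

test_that("network construction applies the double admissibility rule", {
  g <- build_network(toy_edges())
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::V(g)$name, c("c1", "c2", "t1", "t2"))

  ref <- data.frame(target_id = c("t1", "t2"), ref_score = c(9.0, 9.8))
  g2 <- build_network(toy_edges(), threshold = 9, reference_scores = ref)
  # c1-t1: 9.5 > 9 and > 9.0 -> admitted; c1-t2: 10 > 9 and > 9.8 ->
  # admitted; c2-t2: 8.5 below the threshold -> dropped
  expect_equal(igraph::ecount(g2), 2)
  expect_false("c2" %in% igraph::V(g2)$name)  # isolated nodes are dropped

  ref_hi <- data.frame(target_id = c("t1", "t2"), ref_score = c(9.8, 10.5))
  g3 <- build_network(toy_edges(), threshold = 9, reference_scores = ref_hi)
  # 9.5 > 9 but below reference 9.8; 10 > 9 but below 10.5
  expect_equal(igraph::ecount(g3), 0)

  expect_error(
    build_network(toy_edges(), threshold = 9,
                  reference_scores = data.frame(target_id = "t1",
                                                ref_score = 1)),
    "t2")
})

test_that("duplicate pairs are aggregated by best score before filtering", {
  e <- data.frame(compound_id = c("c1", "c1"), target_id = c("t1", "t1"),
                  score = c(8, 9.5))
  ref <- data.frame(target_id = "t1", ref_score = 5)
  g <- build_network(e, threshold = 9, reference_scores = ref)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$score, 9.5)
})

test_that("raising the threshold never adds edges", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      e <- random_bipartite_edges(8, 6)
      ref <- data.frame(target_id = unique(e$target_id),
                        ref_score = stats::runif(length(unique(e$target_id)), 0, 6))
      last <- Inf
      for (th in c(1, 3, 5, 7, 9)) {
        g <- build_network(e, threshold = th, reference_scores = ref)
        expect_lte(igraph::ecount(g), last)
        last <- igraph::ecount(g)
      }
    }
  })
})

test_that("degree equals neighbor count and adjacency row sums", {
  star <- data.frame(compound_id = "c1", target_id = paste0("t", 1:5),
                     score = 1:5)
  cen <- node_centrality(build_network(star))
  expect_equal(cen$degree[cen$node_id == "c1"], 5L)
  expect_true(all(cen$degree[cen$partition == "target"] == 1L))

  withr::with_seed(7, e <- random_bipartite_edges(6, 5))
  g <- build_network(e)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  cen2 <- node_centrality(g)
  expect_equal(cen2$degree, unname(rowSums(A)[cen2$node_id]))
})

test_that("betweenness matches hand values and the walk-count oracle", {
  path3 <- data.frame(compound_id = c("b", "b"), target_id = c("a", "c"),
                      score = 1)
  cen <- node_centrality(build_network(path3))
  expect_equal(cen$betweenness[cen$node_id == "b"], 1.0)
  expect_equal(cen$betweenness[cen$node_id != "b"], c(0, 0))

  star <- data.frame(compound_id = "hub", target_id = paste0("t", 1:5),
                     score = 1)
  cen_s <- node_centrality(build_network(star))
  expect_equal(cen_s$betweenness[cen_s$node_id == "hub"], 1.0)

  withr::with_seed(99, {
    for (rep in 1:20) {
      g <- build_network(random_bipartite_edges(sample(3:6, 1),
                                                sample(3:6, 1)))
      cen_r <- node_centrality(g)
      oracle <- brute_betweenness(g)
      expect_equal(cen_r$betweenness, unname(oracle), tolerance = 1e-10)
    }
  })
})

test_that("components are sized, sorted and tie-broken deterministically", {
  one <- build_network(toy_edges())
  comp <- graph_components(one)
  expect_equal(comp$n_components, 1)
  expect_equal(comp$giant_fraction, 1.0)

  two <- build_network(data.frame(
    compound_id = c("c1", "c2"), target_id = c("t1", "t2"), score = 1))
  comp2 <- graph_components(two)
  expect_equal(comp2$sizes, c(2L, 2L))
  expect_equal(comp2$giant_fraction, 0.5)
  # equal sizes: the component holding the smallest id comes first
  expect_equal(unname(comp2$membership[c("c1", "c2")]), c(1L, 2L))
})

test_that("mean shortest path averages over connected pairs only", {
  path3 <- data.frame(compound_id = c("b", "b"), target_id = c("a", "c"),
                      score = 1)
  expect_equal(mean_shortest_path(build_network(path3)), 4 / 3)

  k22 <- data.frame(compound_id = rep(c("c1", "c2"), each = 2),
                    target_id = rep(c("t1", "t2"), 2), score = 1)
  expect_equal(mean_shortest_path(build_network(k22)), 4 / 3)

  star <- data.frame(compound_id = "hub", target_id = paste0("t", 1:4),
                     score = 1)
  expect_equal(mean_shortest_path(build_network(star)), 1.6)

  # disconnected pairs are excluded, not averaged as infinities
  two <- build_network(data.frame(
    compound_id = c("c1", "c2"), target_id = c("t1", "t2"), score = 1))
  expect_equal(mean_shortest_path(two), 1.0)
})

test_that("density follows the general-graph convention", {
  k22 <- build_network(data.frame(
    compound_id = rep(c("c1", "c2"), each = 2),
    target_id = rep(c("t1", "t2"), 2), score = 1))
  expect_equal(network_density(k22), 2 * 4 / (4 * 3))
  star <- build_network(data.frame(
    compound_id = "hub", target_id = paste0("t", 1:5), score = 1))
  expect_equal(network_density(star), 1 / 3)
})

test_that("handshake and edge-count identities hold on random networks", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      g <- build_network(random_bipartite_edges(7, 5))
      cen <- node_centrality(g)
      st <- network_stats(g)
      e <- igraph::ecount(g)
      expect_equal(sum(cen$degree[cen$partition == "compound"]), e)
      expect_equal(sum(cen$degree[cen$partition == "target"]), e)
      expect_equal(st$mean_targets_per_compound * st$n_compounds,
                   st$mean_hits_per_target * st$n_targets)
      expect_equal(st$density, st$mean_degree / (st$n_compounds +
                                                   st$n_targets - 1))
    }
  })
})

test_that("log-log regression recovers a constructed power law", {
  k <- 1:20
  freq <- round(1000 * k^(-2))
  degrees <- rep(k, freq)
  fit <- fit_power_law(degrees)
  expect_lt(abs(fit$gamma - (-2)), 0.05)
  expect_lt(fit$r, -0.99)  # essentially perfect log-log line
  expect_gt(fit$a, 0)

  expect_error(fit_power_law(rep(4, 50)), "3 distinct")
  expect_error(fit_power_law(c(1, 1, 2, 2)), "3 distinct")
})

test_that("hubs and bottlenecks are ranked with the stated tie-breaks", {
  cen <- data.frame(
    node_id = c("a", "b", "c", "d"),
    partition = "compound",
    degree = c(5L, 3L, 3L, 1L),
    betweenness = c(0.9, 0.1, 0.4, 0.8))
  rk <- rank_hubs_bottlenecks(cen, top_k = 4)
  expect_equal(rk$hubs$node_id, c("a", "c", "b", "d"))       # degree, then btw
  expect_equal(rk$bottlenecks$node_id, c("a", "d", "c", "b")) # btw, then degree
  tie <- cen; tie$degree <- 2L; tie$betweenness <- 0.5
  expect_equal(rank_hubs_bottlenecks(tie, top_k = 4)$hubs$node_id,
               c("a", "b", "c", "d"))                         # id tie-break
})

test_that("hit rate equals an exhaustive per-compound scan", {
  all_pass <- data.frame(compound_id = c("c1", "c2"),
                         target_id = c("t1", "t1"), score = c(9.5, 10))
  ref <- data.frame(target_id = "t1", ref_score = 5)
  expect_equal(hit_rate(all_pass, 9, ref), 1.0)
  expect_equal(hit_rate(all_pass, 11, ref), 0.0)

  withr::with_seed(17, {
    e <- random_bipartite_edges(15, 8, p = 0.5)
    tg <- unique(e$target_id)
    ref2 <- data.frame(target_id = tg,
                       ref_score = stats::runif(length(tg), 2, 8))
    th <- 6
    # brute-force scan over the raw table
    refv <- stats::setNames(ref2$ref_score, ref2$target_id)
    pass <- e$score > th & e$score > refv[e$target_id]
    expected <- length(unique(e$compound_id[pass])) /
      length(unique(e$compound_id))
    expect_equal(hit_rate(e, th, ref2), expected)
  })
})

test_that("published network characteristics satisfy the analytic identities", {
  r <- dtn_reference_stats
  implied <- implied_density(r$n_compounds + r$n_targets, r$mean_degree)
  # published densities are printed to four decimal places
  expect_equal(round(implied, 4), r$density)
  hits <- implied_hits_per_target(r$mean_targets_per_compound[1:2],
                                  r$n_compounds[1:2], r$n_targets[1:2])
  expect_equal(round(hits[1]), r$mean_hits_per_target[1])   # printed as 25
  expect_equal(round(hits[2], 2), r$mean_hits_per_target[2])# printed as 5.35
})
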