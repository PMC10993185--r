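net_ab <- function() {
  # A->B 2, B->A 1, B->C 1
  build_network(data.frame(participant = "p1",
                           source = c("A", "A", "B", "B"),
                           target = c("B", "B", "A", "C"),
                           stringsAsFactors = FALSE))
}

test_that("strength sums incoming and outgoing weights", {
  net <- net_ab()
  expect_equal(strength(net, "A"), 3)   # out 2 + in 1
  expect_equal(strength(net, "B"), 4)   # out 2 + in 2
  expect_equal(strength(net, "C"), 1)
  iso <- build_network(data.frame(participant = character(0),
                                  source = character(0), target = character(0),
                                  stringsAsFactors = FALSE),
                       nodes = "Z")
  expect_equal(strength(iso, "Z"), 0)
  expect_error(strength(net, "Q"), "unknown node")
})

test_that("group strength counts internal edges twice unless excluded", {
  net <- net_ab()
  expect_equal(group_strength(net, c("A", "B")), 7)
  expect_equal(group_strength(net, c("A", "B"), exclude_internal = TRUE), 1)
  # handshake identity: all nodes, default flag
  expect_equal(group_strength(net, net$nodes), 2 * sum(net$edges$weight))
  expect_error(group_strength(net, character(0)), "non-empty")
})

test_that("WDC matches the closed-form worked values", {
  expect_equal(weighted_degree_centrality(c(1, 1, 1, 1)), 4)
  expect_equal(weighted_degree_centrality(c(1, 1, 2)), 2.5)
  expect_equal(weighted_degree_centrality(5), 1)
  expect_equal(weighted_degree_centrality(0.01), 1)
  expect_error(weighted_degree_centrality(numeric(0)), "DC >= 1")
  expect_error(weighted_degree_centrality(c(1, -2)), "positive")
})

test_that("WDC is bounded by [1, DC], scale-free and order-invariant", {
  set.seed(501)
  for (i in 1:500) {
    dc <- sample(1:12, 1)
    w <- runif(dc, 0.1, 20)
    v <- weighted_degree_centrality(w)
    expect_gte(v, 1); expect_lte(v, dc + 1e-12)
    expect_equal(weighted_degree_centrality(w * runif(1, 0.01, 50)), v,
                 tolerance = 1e-9)
    expect_equal(weighted_degree_centrality(w[sample.int(dc)]), v, tolerance = 1e-12)
  }
  # equality at DC iff weights uniform
  expect_equal(weighted_degree_centrality(rep(3.7, 6)), 6)
  expect_lt(weighted_degree_centrality(c(rep(1, 5), 1.01)), 6)
})

test_that("WDC of a network node uses its outgoing profile", {
  net <- net_ab()
  expect_equal(weighted_degree_centrality(net, "B"),
               weighted_degree_centrality(c(1, 1)))
  expect_error(weighted_degree_centrality(net, "C"), "no outgoing")
})

test_that("uniformity is the negated chi-square statistic of the edge weights", {
  expect_equal(uniformity(c(2, 2, 2)), 0)
  expect_equal(uniformity(c(1, 3)), -1)
  expect_equal(uniformity(c(1, 1, 4)), -3)
  expect_error(uniformity(numeric(0)), "at least one edge")
})

test_that("uniformity is non-positive, zero only for equal weights, and decreases with spread", {
  set.seed(502)
  for (i in 1:200) {
    w <- sample.int(20, sample(2:10, 1), replace = TRUE)
    u <- uniformity(w)
    expect_lte(u, 0)
    if (length(unique(w)) == 1) expect_equal(u, 0) else expect_lt(u, 0)
  }
  # moving weight from a below-mean edge to an above-mean edge (mean fixed)
  w <- c(2, 4, 6)
  expect_lt(uniformity(c(1, 4, 7)), uniformity(w))
})

test_that("cut sizes count both directions and normalize by total weight", {
  net <- build_network(data.frame(participant = "p1",
                                  source = c("A", "A", "A", "B", "B"),
                                  target = c("B", "B", "B", "C", "C"),
                                  stringsAsFactors = FALSE))
  # edges A->B 3, B->C 2
  expect_equal(cut_size(net, "A", c("B", "C")), 3)
  expect_equal(normalized_cut_size(net, "A", c("B", "C")), 0.6)
  expect_equal(cut_size(net, c("A", "B"), "C"), 2)
  # no crossing edges
  net2 <- build_network(data.frame(participant = "p", source = c("A", "C"),
                                   target = c("B", "D"), stringsAsFactors = FALSE))
  expect_equal(cut_size(net2, c("A", "B"), c("C", "D")), 0)
  # every edge crossing: normalized 1
  expect_equal(normalized_cut_size(net2, c("A", "C"), c("B", "D")), 1)
  expect_error(cut_size(net, c("A", "B"), c("B", "C")), "disjoint")
  expect_error(cut_size(net, character(0), "B"), "non-empty")
})

test_that("cut size plus internal weights conserves the total on covering partitions", {
  set.seed(503)
  for (i in 1:100) {
    net <- random_network(sample(4:7, 1))
    if (nrow(net$edges) == 0) next
    ns <- net$nodes
    s <- sample(ns, sample(seq_len(length(ns) - 1), 1))
    t <- setdiff(ns, s)
    internal <- function(grp) {
      e <- net$edges
      sum(e$weight[e$source %in% grp & e$target %in% grp])
    }
    expect_equal(cut_size(net, s, t) + internal(s) + internal(t),
                 sum(net$edges$weight))
  }
})

test_that("maximal cliques require an undirected network and match hand cases", {
  tri <- build_network(data.frame(
    participant = "p1",
    source = c("A", "B", "A", "C"),
    target = c("B", "C", "C", "D"), stringsAsFactors = FALSE))
  expect_error(maximal_cliques(tri), "to_undirected")
  cl <- maximal_cliques(to_undirected(tri))
  expect_equal(cl, list(c("C", "D"), c("A", "B", "C")))
  st <- clique_stats(to_undirected(tri))
  expect_equal(st$count, 2L)
  expect_equal(st$mean_size, 2.5)

  # complete graph on 4 nodes: a single clique
  pairs <- t(combn(LETTERS[1:4], 2))
  k4 <- to_undirected(build_network(data.frame(
    participant = "p", source = pairs[, 1], target = pairs[, 2],
    stringsAsFactors = FALSE)))
  expect_equal(maximal_cliques(k4), list(LETTERS[1:4]))

  # edgeless graph: three singleton cliques, reported separately
  iso <- to_undirected(build_network(
    data.frame(participant = character(0), source = character(0),
               target = character(0), stringsAsFactors = FALSE),
    nodes = c("A", "B", "C")))
  st0 <- clique_stats(iso)
  expect_equal(st0$count, 3L)
  expect_equal(st0$mean_size, 1)
  expect_equal(st0$count_size2, 0L)
  expect_true(is.na(st0$mean_size2))
})

test_that("clique enumeration agrees with exhaustive subset search on random graphs", {
  set.seed(504)
  for (i in 1:60) {
    net <- random_network(sample(3:8, 1), p_edge = runif(1, 0.15, 0.7))
    und <- to_undirected(net)
    expect_equal(maximal_cliques(und),
                 oracle_maximal_cliques(und$nodes, und$edges))
  }
})

test_that("metrics reports are reproducible and serialize to JSON", {
  set.seed(505)
  net <- random_network(5)
  rep1 <- metrics_report(net, groups = list(g = c("A", "B")),
                         partitions = list(p = list(s = c("A", "B"), t = c("C", "D", "E"))))
  rep2 <- metrics_report(net, groups = list(g = c("A", "B")),
                         partitions = list(p = list(s = c("A", "B"), t = c("C", "D", "E"))))
  expect_identical(rep1, rep2)
  path <- tempfile(fileext = ".json")
  write_metrics(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$uniformity, rep1$uniformity)
  expect_equal(back$cuts$p$cut_size, rep1$cuts$p$cut_size)
  expect_equal(sort(names(back$strength)), sort(net$nodes))
})
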