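# Centrality measures: closed-form cases, then brute-force oracles on
# random graphs.

path_graph <- function(names) {
  igraph::make_graph(rep(names, each = 2)[-c(1, 2 * length(names))],
                     directed = FALSE)
}

test_that("projection collapses parallel and antiparallel edges and drops
           self-loops", {
  net <- assoc_network(edges = rbind(
    ed("X", "gene", "Y", "gene", "association"),
    ed("X", "gene", "Y", "gene", "protein-protein"),
    ed("X", "gene", "Y", "gene", "genetic-regulation"),
    ed("Y", "gene", "X", "gene", "expression")))
  g <- project_simple_undirected(net)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::vcount(g), 2L)

  loop <- assoc_network(edges = ed("X", "gene", "X", "gene",
                                   "association"))
  expect_equal(igraph::ecount(project_simple_undirected(loop)), 0L)
})

test_that("degree centrality matches closed forms and the brute-force
           count", {
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "a", "b", "c")
  dc <- degree_centrality(star)
  expect_equal(unname(dc["hub"]), 1.0)
  expect_equal(unname(dc["a"]), 1 / 3)

  p3 <- path_graph(c("a", "b", "c"))
  expect_equal(unname(degree_centrality(p3)[c("a", "b")]), c(0.5, 1.0))

  set.seed(42)
  for (i in 1:5) {
    g <- rnd_graph(8, 0.4)
    expect_equal(degree_centrality(g), oracle_degree_centrality(g))
  }

  expect_error(degree_centrality(igraph::make_empty_graph(1,
                                                          directed = FALSE)),
               "at least 2")
})

test_that("closeness centrality uses reachable-set scaling", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(unname(closeness_centrality(tri)), rep(1, 3))

  p3 <- path_graph(c("a", "b", "c"))
  expect_equal(unname(closeness_centrality(p3)["a"]), 2 / 3)

  # two disjoint dyads: each vertex reaches 1 other at distance 1:
  # (1/1) * (1/3) = 1/3
  dyads <- igraph::make_graph(c("a", "b", "c", "d"), directed = FALSE)
  expect_equal(unname(closeness_centrality(dyads)), rep(1 / 3, 4))

  # isolated vertex -> 0
  iso <- igraph::make_empty_graph(0, directed = FALSE) +
    igraph::vertices("a", "b", "c") + igraph::edges(c("a", "b"))
  expect_equal(unname(closeness_centrality(iso)["c"]), 0)

  set.seed(43)
  for (i in 1:5) {
    g <- rnd_graph(8, 0.3)
    expect_equal(closeness_centrality(g), oracle_closeness_centrality(g),
                 tolerance = 1e-12)
  }
})

test_that("betweenness centrality matches enumeration of shortest paths", {
  p3 <- path_graph(c("a", "b", "c"))
  expect_equal(unname(betweenness_centrality(p3)["b"]), 1.0)

  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "a", "b", "c")
  bc <- betweenness_centrality(star)
  expect_equal(unname(bc["hub"]), 1.0)
  expect_equal(unname(bc["a"]), 0)

  c4 <- igraph::make_ring(4)
  igraph::V(c4)$name <- letters[1:4]
  expect_equal(length(unique(round(betweenness_centrality(c4), 12))), 1L)

  # graphs below the normalization threshold give all-zero profiles
  dyad <- igraph::make_graph(c("a", "b"), directed = FALSE)
  expect_equal(unname(betweenness_centrality(dyad)), c(0, 0))

  set.seed(44)
  for (i in 1:6) {
    g <- rnd_graph(sample(4:8, 1), 0.45)
    expect_equal(betweenness_centrality(g),
                 oracle_betweenness_centrality(g), tolerance = 1e-10)
  }
})

test_that("centralities are invariant under vertex relabeling", {
  set.seed(45)
  g <- rnd_graph(10, 0.3)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  for (f in list(degree_centrality, closeness_centrality,
                 betweenness_centrality)) {
    v1 <- f(g)
    v2 <- f(g2)
    expect_equal(v2[names(v1)], v1, tolerance = 1e-12)
  }
})

test_that("per-symbol profile aggregates gene/protein forms by maximum", {
  # star around the TNF protein; the TNF gene hangs off a leaf
  net <- assoc_network(edges = rbind(
    ed("TNF", "protein", "A", "gene", "association"),
    ed("TNF", "protein", "B", "gene", "association"),
    ed("TNF", "protein", "C", "gene", "association"),
    ed("TNF", "gene", "A", "gene", "association")))
  prof <- gene_centrality_profile(net)
  pv <- attr(prof, "vertex")
  tnf_forms <- pv[pv$symbol == "TNF", ]
  expect_equal(nrow(tnf_forms), 2L)
  expect_equal(prof$dc[prof$symbol == "TNF"], max(tnf_forms$dc))
  expect_equal(prof$cc[prof$symbol == "TNF"], max(tnf_forms$cc))
  expect_equal(prof$mean3,
               (prof$dc + prof$cc + prof$bc) / 3)

  # single-form symbols: aggregation is the identity
  single <- assoc_network(edges = ed("X", "gene", "Y", "gene",
                                     "association"))
  prof1 <- gene_centrality_profile(single)
  expect_equal(prof1$dc, attr(prof1, "vertex")$dc)
})
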