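s5 <- make_fixture("star", n = 5)
k3 <- make_fixture("complete", n = 3)
k4 <- make_fixture("complete", n = 4)

test_that("degree-type measures match closed forms", {
  expect_equal(unname(scores_of(s5, "degree")["v1"]), 4)
  expect_equal(unname(scores_of(k3, "local_clustering")), rep(1, 3))
  expect_equal(unname(scores_of(s5, "leverage")["v1"]), 0.6)
  expect_equal(unname(scores_of(k4, "kcore")), rep(3, 4))
  expect_equal(unname(scores_of(k3, "topological_coefficient")), rep(1, 3))
  expect_equal(stats::sd(scores_of(make_fixture("cycle", n = 5),
                                   "semilocal")), 0)
  gd <- graph_from_edges("a", "b", "a", "c", directed = TRUE)
  expect_equal(unname(scores_of(gd, "degree", list(mode = "out"))),
               c(2, 0, 0))
  expect_equal(unname(scores_of(gd, "degree", list(mode = "in"))),
               c(0, 1, 1))
  gw <- graph_from_edges("a", "b", "a", "c", weights = c(2, 0.5))
  expect_equal(unname(scores_of(gw, "strength")), c(2.5, 2, 0.5))
})

test_that("lobby index is the h-index of neighbor degrees", {
  # hub with neighbor degrees {4, 3, 1}: two neighbors with degree >= 2
  g <- graph_from_edges(
    "v", "a", "v", "b", "v", "c",
    "a", "a1", "a", "a2", "a", "a3",        # deg(a) = 4
    "b", "b1", "b", "b2")                   # deg(b) = 3, deg(c) = 1
  expect_equal(unname(scores_of(g, "lobby")["v"]), 2)
  # lobby bounded by degree; brute force over candidate l values
  for (seed in 1:5) {
    gr <- random_connected(9, 0.35, seed)
    lb <- scores_of(gr, "lobby")
    dg <- igraph::degree(gr)
    expect_true(all(lb <= dg))
    for (v in seq_len(9)) {
      nd <- dg[as.integer(igraph::neighbors(gr, v))]
      brute <- 0
      for (l in seq_len(max(0, length(nd))))
        if (sum(nd >= l) >= l) brute <- l
      expect_equal(unname(lb[v]), brute)
    }
  }
})

test_that("MNC/DMNC score the largest neighborhood component", {
  # neighborhood of v: component {a, b, c} with 2 edges, plus isolated d
  g <- graph_from_edges("v", "a", "v", "b", "v", "c", "v", "d",
                        "a", "b", "b", "c")
  expect_equal(unname(scores_of(g, "mnc")["v"]), 3)
  expect_equal(unname(scores_of(g, "dmnc", list(epsilon = 1.7))["v"]),
               2 / 3^1.7)
  for (seed in 1:5) {
    gr <- random_connected(8, 0.4, seed)
    expect_true(all(scores_of(gr, "mnc") <= igraph::degree(gr)))
    sv <- scores_of(gr, "dmnc")
    expect_true(all(sv[scores_of(gr, "mnc") <= 1] == 0))
  }
})

test_that("cross-clique connectivity equals Bron-Kerbosch enumeration", {
  for (seed in 1:6) {
    g <- random_connected(9, 0.45, seed)
    expect_equal(unname(scores_of(g, "cross_clique")),
                 brute_clique_membership(g))
  }
})

test_that("Burt's constraint agrees with the reference implementation", {
  for (seed in 1:5) {
    g <- random_connected(8, 0.4, seed)
    expect_equal(unname(scores_of(g, "burt_constraint")),
                 unname(igraph::constraint(g)), tolerance = 1e-10)
  }
  g <- igraph::add_vertices(make_fixture("path", n = 2), 1, name = "c")
  expect_warning(cs <- neighborhood_score(g, "burt_constraint")$scores,
                 "isolated")
  expect_equal(unname(cs), c(1, 1, 0))
})

test_that("ClusterRank and diffusion degree follow their formulas", {
  # triangle a-b-c plus pendant d on a: c(a) = 1/3 (one of three pairs)
  g <- graph_from_edges("a", "b", "b", "c", "a", "c", "a", "d")
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  deg <- igraph::degree(g)
  want_a <- unname(10^(-cc[1]) * sum(deg[c(2, 3, 4)] + 1))
  expect_equal(unname(scores_of(g, "clusterrank")["a"]), want_a)
  expect_equal(unname(scores_of(g, "diffusion_degree", list(lambda = 0.5))),
               unname(0.5 * deg + 0.5 * c(2 + 2 + 1, 3 + 2, 3 + 2, 3)))
  # directed variant uses out-neighborhoods
  gd <- graph_from_edges("a", "b", "a", "c", "b", "c", directed = TRUE)
  expect_equal(unname(scores_of(gd, "clusterrank")["b"]),
               unname(10^(-igraph::transitivity(igraph::as_undirected(gd),
                                                type = "localundirected",
                                                isolates = "zero")[2]) * 1))
})

test_that("graphlet orbit counts match exhaustive subgraph enumeration", {
  brute_orbits <- function(g, max_size) {
    n <- igraph::vcount(g)
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
    counts <- matrix(0L, n, if (max_size == 3) 4L else 15L)
    for (k in 2:max_size) for (S in utils::combn(n, k, simplify = FALSE)) {
      sub <- A[S, S, drop = FALSE]
      din <- rowSums(sub)
      comp_ok <- igraph::is_connected(
        igraph::graph_from_adjacency_matrix(sub, mode = "undirected"))
      if (!comp_ok) next
      orb <- netcentral:::classify_orbits(k, as.integer(din))
      for (i in seq_len(k))
        counts[S[i], orb[i] + 1L] <- counts[S[i], orb[i] + 1L] + 1L
    }
    counts
  }
  for (seed in 1:4) {
    g <- random_connected(8, 0.45, seed)
    got <- graphlet_orbit_counts(g, max_size = 4)
    expect_equal(unname(got), unname(brute_orbits(g, 4)),
                 info = paste("seed", seed))
  }
  g <- random_connected(8, 0.45, 9)
  expect_equal(unname(graphlet_orbit_counts(g, max_size = 3)),
               unname(brute_orbits(g, 3)))
  # scalar reduction = total graphlet incidences
  sv <- scores_of(g, "graphlet_degree")
  expect_equal(unname(sv), rowSums(brute_orbits(g, 4)))
})

test_that("local measures never decrease when an edge is added at v", {
  for (seed in 1:4) {
    g <- random_connected(8, 0.3, seed)
    non_edges <- which(!as.matrix(igraph::as_adjacency_matrix(g)) &
                         upper.tri(diag(8)), arr.ind = TRUE)
    if (!nrow(non_edges)) next
    pick <- non_edges[1, ]
    g2 <- igraph::add_edges(g, c(pick[1], pick[2]))
    for (id in c("degree", "lobby", "mnc")) {
      s1 <- scores_of(g, id); s2 <- scores_of(g2, id)
      expect_true(all(s2[c(pick[1], pick[2])] >= s1[c(pick[1], pick[2])]),
                  info = id)
    }
  }
})

test_that("integrality holds for counting measures", {
  g <- random_connected(9, 0.4, 3)
  for (id in c("degree", "lobby", "kcore", "mnc", "cross_clique",
               "graphlet_degree", "geodesic_kpath"))
    expect_equal(scores_of(g, id), round(scores_of(g, id)), info = id)
})
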