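s5 <- make_fixture("star", n = 5)
c4 <- make_fixture("cycle", n = 4)
c5 <- make_fixture("cycle", n = 5)

test_that("eigenvector and subgraph centrality match closed forms", {
  expect_equal(unname(scores_of(s5, "eigenvector")[c("v1", "v2")]),
               c(1, 0.5))
  expect_equal(unname(scores_of(make_fixture("complete", n = 2),
                                "subgraph")), rep(cosh(1), 2))
  # subgraph centrality >= 1 and spectral form on random graphs
  for (seed in 1:4) {
    g <- random_connected(7, 0.4, seed)
    sg <- scores_of(g, "subgraph")
    expect_true(all(sg >= 1))
    ed <- eigen(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)),
                symmetric = TRUE)
    expect_equal(unname(sg),
                 rowSums(ed$vectors^2 * rep(exp(ed$values),
                                            each = nrow(ed$vectors))),
                 tolerance = 1e-10)
    ev <- scores_of(g, "eigenvector")
    ref <- igraph::eigen_centrality(g)$vector
    expect_equal(unname(ev), unname(ref / max(ref)), tolerance = 1e-6)
  }
})

test_that("katz linear solve equals the truncated power series", {
  for (seed in 1:5) {
    g <- random_connected(8, 0.4, seed)
    A <- t(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
    lam <- max(Mod(eigen(A, only.values = TRUE)$values))
    a <- 0.5 / lam
    series <- rep(0, 8); term <- rep(1, 8)
    for (k in 1:60) { term <- a * A %*% term; series <- series + term }
    expect_equal(unname(scores_of(g, "katz")), as.numeric(series),
                 tolerance = 1e-8)
  }
  g <- make_fixture("path", n = 3)
  expect_error(centrality_score(g, "katz", list(alpha = 2)), "diverges")
})

test_that("alpha, Bonacich and Hubbell solve their defining systems", {
  g <- random_connected(7, 0.45, 2)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  lam <- max(Mod(eigen(A, only.values = TRUE)$values))
  a <- 0.5 / lam
  x <- scores_of(g, "alpha_centrality", list(alpha = a, exo = 1))
  expect_equal(as.numeric((diag(7) - a * t(A)) %*% x), rep(1, 7),
               tolerance = 1e-10)
  b <- 0.9 / lam
  cb <- scores_of(g, "bonacich_power", list(alpha = 2, beta = b))
  expect_equal(as.numeric((diag(7) - b * A) %*% cb / 2),
               as.numeric(A %*% rep(1, 7)), tolerance = 1e-8)
  w <- 0.5 / lam
  h <- scores_of(g, "hubbell", list(weight_factor = w, exo = 2))
  expect_equal(as.numeric((diag(7) - w * t(A)) %*% h), rep(2, 7),
               tolerance = 1e-10)
})

test_that("pagerank is a probability vector matching the reference", {
  expect_equal(unname(scores_of(c4, "pagerank")), rep(0.25, 4))
  for (seed in 1:3) {
    g <- random_connected(9, 0.35, seed)
    pr <- scores_of(g, "pagerank")
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_equal(unname(pr), igraph::page_rank(g, damping = 0.85)$vector,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # dangling vertices teleport uniformly; still sums to one
  gd <- graph_from_edges("a", "b", "b", "c", "c", "a", "a", "d",
                         directed = TRUE)
  expect_equal(sum(scores_of(gd, "pagerank")), 1, tolerance = 1e-9)
})

test_that("leaderrank is constant on symmetric graphs and mass-conserving", {
  lr <- scores_of(c5, "leaderrank")
  expect_equal(stats::sd(lr), 0, tolerance = 1e-9)
  g <- random_connected(8, 0.4, 4)
  lr2 <- scores_of(g, "leaderrank")
  expect_equal(sum(lr2), 8, tolerance = 1e-6)  # n units incl. ground share
  expect_true(all(lr2 > 0))
})

test_that("HITS authority equals eigenvector centrality on undirected
           graphs", {
  for (seed in 1:3) {
    g <- random_connected(8, 0.4, seed)
    au <- scores_of(g, "hits")
    ev <- scores_of(g, "eigenvector")
    expect_equal(unname(au / max(au)), unname(ev), tolerance = 1e-6)
  }
  sv <- suppressWarnings(centrality_score(random_connected(6, 0.5, 1),
                                          "hits"))
  expect_true(is.numeric(sv$extra$hub))
})

test_that("salsa authority reduces to in-degree share of the arcs", {
  gd <- graph_from_edges("h1", "a1", "h1", "a2", "h2", "a2", "h2", "a3",
                         "x", "y", directed = TRUE)
  sa <- scores_of(gd, "salsa")
  din <- igraph::degree(gd, mode = "in")
  expect_equal(unname(sa), unname(din / igraph::ecount(gd)),
               tolerance = 1e-8)
  g <- random_connected(7, 0.4, 5)            # undirected: edges = two arcs
  expect_equal(unname(scores_of(g, "salsa")),
               unname(igraph::degree(g) / (2 * igraph::ecount(g))),
               tolerance = 1e-8)
})

test_that("laplacian centrality equals recompute-by-removal exactly", {
  expect_equal(unname(scores_of(make_fixture("path", n = 3), "laplacian")),
               c(6, 10, 6))
  lap_energy <- function(g) {
    A <- as.matrix(igraph::as_adjacency_matrix(
      g, attr = if (is_weighted_graph(g)) "weight" else NULL,
      sparse = FALSE))
    L <- diag(rowSums(A)) - A
    sum(diag(L %*% L))
  }
  for (seed in 1:4) {
    g <- random_connected(7, 0.45, seed, weighted = (seed %% 2 == 0))
    if (is_weighted_graph(g))
      igraph::E(g)$weight <- round(igraph::E(g)$weight)  # integer weights
    g <- igraph::delete_edges(g, which(igraph::E(g)$weight == 0))
    sv <- scores_of(g, "laplacian")
    E0 <- lap_energy(g)
    for (v in seq_len(igraph::vcount(g)))
      expect_equal(unname(sv[v]),
                   E0 - lap_energy(igraph::delete_vertices(g, v)))
  }
})

test_that("entropy centrality: exact path-transfer distribution on small
           graphs, seeded Monte Carlo above the exact limit", {
  # star center: flow always stops at a uniformly chosen leaf
  ent <- scores_of(s5, "entropy")
  expect_equal(unname(ent["v1"]), log2(4))
  # path end: deterministic absorption at the far end
  expect_equal(unname(scores_of(make_fixture("path", n = 4),
                                "entropy")["v1"]), 0)
  g <- random_connected(7, 0.5, 8)
  exact <- scores_of(g, "entropy")
  mc <- scores_of(g, "entropy", list(exact_limit = 0, samples = 4000,
                                     seed = 11))
  expect_equal(unname(mc), unname(exact), tolerance = 0.1)
  mc2 <- scores_of(g, "entropy", list(exact_limit = 0, samples = 4000,
                                      seed = 11))
  expect_identical(mc, mc2)
})

test_that("community centrality follows the leading-eigenvector basis", {
  g <- random_connected(8, 0.35, 6)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  k <- rowSums(A)
  B <- A - outer(k, k) / sum(k)
  ed <- eigen(B, symmetric = TRUE)
  pos <- ed$values > 1e-12
  want <- sqrt(rowSums(ed$vectors[, pos, drop = FALSE]^2 *
                         rep(ed$values[pos], each = 8)))
  expect_equal(unname(scores_of(g, "community")), want, tolerance = 1e-10)
})
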