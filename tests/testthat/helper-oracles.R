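# Independent brute-force oracles used across the suites.  All operate on
# plain matrices, never on the package's own shortest-path machinery.

# Floyd-Warshall all-pairs distances from a weight matrix (0 = no edge)
fw_distances <- function(g) {
  n <- igraph::vcount(g)
  W <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if (is_weighted_graph(g)) "weight" else NULL, sparse = FALSE))
  D <- matrix(Inf, n, n)
  D[W > 0] <- W[W > 0]
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  D
}

# geodesic path counts by dynamic programming over the Floyd-Warshall
# distance matrix (sigma[s, t] = number of shortest s-t paths)
geodesic_counts <- function(g, D = fw_distances(g)) {
  n <- nrow(D)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  ord <- order(D)               # fill in increasing distance
  for (idx in ord) {
    s <- (idx - 1) %% n + 1; t <- (idx - 1) %/% n + 1
    if (s == t || !is.finite(D[s, t]) || D[s, t] == 0) next
    pred <- which(A[, t] & D[s, ] + 1 == D[s, t] &
                    is.finite(D[s, ]))
    if (D[s, t] == 1) sigma[s, t] <- 1
    else sigma[s, t] <- sum(sigma[s, pred])
  }
  sigma
}

# betweenness / stress by direct summation over (s, v, t) triples
brute_betweenness_stress <- function(g) {
  D <- fw_distances(g)
  sigma <- geodesic_counts(g, D)
  n <- nrow(D)
  bt <- st <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(D[s, t]) || sigma[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        np <- sigma[s, v] * sigma[v, t]
        bt[v] <- bt[v] + np / sigma[s, t]
        st[v] <- st[v] + np
      }
    }
  }
  if (!igraph::is_directed(g)) { bt <- bt / 2; st <- st / 2 }
  list(betweenness = bt, stress = st)
}

# maximal cliques containing each vertex, by pivot-free Bron-Kerbosch
brute_clique_membership <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  counts <- numeric(n)
  bk <- function(Rset, Pset, Xset) {
    if (!length(Pset) && !length(Xset)) {
      counts[Rset] <<- counts[Rset] + 1
      return()
    }
    for (v in Pset) {
      bk(c(Rset, v), Pset[A[v, Pset]], Xset[A[v, Xset]])
      Pset <- setdiff(Pset, v)
      Xset <- c(Xset, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  counts
}

# exact EPC by enumerating all 2^m edge-retention realizations
brute_epc <- function(g, retention) {
  m <- igraph::ecount(g)
  n <- igraph::vcount(g)
  stopifnot(m <= 12)
  exp_size <- numeric(n)
  for (mask in 0:(2^m - 1)) {
    keep <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    pk <- retention^length(keep) * (1 - retention)^(m - length(keep))
    gs <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
    comp <- igraph::components(gs)
    exp_size <- exp_size + pk * comp$csize[comp$membership]
  }
  exp_size
}

# minimum footrule objective by full permutation search
brute_min_footrule <- function(lists) {
  universe <- sort(unique(unlist(lists)), method = "radix")
  N <- length(universe)
  R <- vapply(lists, function(l) {
    r <- match(universe, l); r[is.na(r)] <- length(l) + 1L; r
  }, numeric(N))
  perms <- perms_of(N)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    cr <- integer(N); cr[perms[i, ]] <- seq_len(N)
    best <- min(best, sum(colSums(abs(R - cr))))
  }
  best
}

perms_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# distance-family formulas re-evaluated directly from a supplied distance
# matrix (used with fw_distances as the independent distance oracle)
oracle_distance_from_D <- function(D, measure, delta = 0.5, k = 3) {
  n <- nrow(D)
  diag(D) <- Inf
  fin <- is.finite(D)
  rr <- rowSums(fin)
  ss <- rowSums(ifelse(fin, D, 0))
  diam <- if (any(fin)) max(D[fin]) else 0
  switch(measure,
    closeness_freeman = ifelse(rr > 0, rr^2 / (ss * max(n - 1, 1)), 0),
    closeness_latora = rowSums(ifelse(fin, 1 / D, 0)),
    closeness_dangalchev = rowSums(ifelse(fin, 2^(-D), 0)),
    barycenter = ifelse(rr > 0, 1 / ss, 0),
    lin = ifelse(rr > 0, (rr + 1)^2 / ss, 0),
    eccentricity = vapply(seq_len(n), function(v)
      if (rr[v] > 0) 1 / max(D[v, fin[v, ]]) else 0, 0),
    radiality = rowSums(ifelse(fin, diam + 1 - D, 0)) / max(n - 1, 1),
    decay = rowSums(ifelse(fin, delta^D, 0)),
    average_distance = ifelse(rr > 0, ss / rr, 0),
    geodesic_kpath = rowSums(fin & D <= k),
    stop("no oracle for ", measure))
}

# helper graph builders ---------------------------------------------------
graph_from_edges <- function(..., directed = FALSE, weights = NULL) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  df <- data.frame(src = e[, 1], dst = e[, 2], stringsAsFactors = FALSE)
  if (!is.null(weights)) df$w <- weights
  as_netgraph(df, directed = directed, weighted = !is.null(weights))
}

random_connected <- function(n, p, seed, weighted = FALSE) {
  g <- with_seed_test(seed, {
    repeat {
      h <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(h)) break
    }
    if (weighted) igraph::E(h)$weight <- round(stats::runif(
      igraph::ecount(h), 0.5, 3), 2)
    h
  })
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  code
}

scores_of <- function(g, id, params = list())
  suppressWarnings(suppressMessages(centrality_score(g, id, params)))$scores
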