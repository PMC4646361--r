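#' Flow / brokerage centrality family
#'
#' Measures of how much traffic a vertex carries: shortest-path
#' betweenness (Brandes accumulation), stress, load (equal splitting at
#' branches), max-flow betweenness, current-flow betweenness and
#' closeness (Laplacian pseudoinverse), Stephenson-Zelen information
#' centrality, communicability betweenness and Markov (mean
#' first-passage) centrality.
#'
#' Conventions: on undirected graphs each unordered source-target pair is
#' counted once; path endpoints are never counted as interior vertices.
#' Weights are read as geodesic distances by the shortest-path measures,
#' as capacities by max-flow betweenness, and as conductances by the
#' electrical measures.  Disconnected graphs are handled per connected
#' component.
#'
#' @param g labelled igraph object, already simplified.
#' @param measure_id one of the family ids (see
#'   \code{list_measures("flow")}).
#' @param params list; \code{normalized} (default \code{FALSE}) divides
#'   betweenness-type totals by \eqn{(n-1)(n-2)/s}, \eqn{s = 2} when
#'   undirected.
#' @return a [score_vector].
#' @examples
#' p4 <- make_fixture(fixture_spec("path", n = 4))
#' flow_score(p4, "betweenness")$scores
#' @export
flow_score <- function(g, measure_id, params = list()) {
  desc <- measure_descriptor(measure_id)
  if (desc$family != "flow")
    stop("'", measure_id, "' is not in the flow family")
  pars <- resolve_params(desc, params)
  labs <- vertex_labels(g)
  n <- length(labs)
  named <- function(x) stats::setNames(as.numeric(x), labs)
  directed <- igraph::is_directed(g)

  raw <- switch(measure_id,
    betweenness = brandes_accumulate(g, kind = "betweenness"),
    stress = brandes_accumulate(g, kind = "stress"),
    load = load_accumulate(g),
    flow_betweenness = flow_betweenness_raw(g),
    current_flow_betweenness = cfb_raw(g),
    current_flow_closeness = cfc_raw(g),
    information = information_raw(g),
    communicability_betweenness = comm_betweenness_raw(g),
    markov = markov_raw(g),
    stop("unhandled flow measure '", measure_id, "'"))

  if (isTRUE(pars$normalized) &&
      measure_id %in% c("betweenness", "stress", "load", "flow_betweenness",
                        "current_flow_betweenness")) {
    s <- if (directed) 1 else 2
    denom <- (n - 1) * (n - 2) / s
    if (denom > 0) raw <- raw / denom
  }
  score_vector(measure_id, named(raw), pars)
}

# single-source shortest paths: distances, path counts sigma, geodesic-DAG
# predecessor lists and a processing order by non-decreasing distance
sssp <- function(adj, wts, s, n) {
  dist <- rep(Inf, n); sigma <- numeric(n); preds <- vector("list", n)
  dist[s] <- 0; sigma[s] <- 1
  if (is.null(wts)) {                       # BFS
    order_out <- integer(0); queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      order_out <- c(order_out, v)
      for (k in seq_along(adj[[v]])) {
        w <- adj[[v]][k]
        if (!is.finite(dist[w])) {
          dist[w] <- dist[v] + 1; queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
  } else {                                  # Dijkstra, O(n^2)
    done <- logical(n)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      v <- cand[which.min(dist[cand])]
      done[v] <- TRUE
      for (k in seq_along(adj[[v]])) {
        w <- adj[[v]][k]; dw <- dist[v] + wts[[v]][k]
        if (dw < dist[w] - 1e-12) {
          dist[w] <- dw; sigma[w] <- sigma[v]; preds[[w]] <- v
        } else if (abs(dw - dist[w]) <= 1e-12) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    order_out <- order(dist)[seq_len(sum(is.finite(dist)))]
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_out)
}

out_adjacency <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (is_weighted_graph(g)) igraph::E(g)$weight else NULL
  adj <- vector("list", n); wts <- if (is.null(w)) NULL else vector("list", n)
  add <- function(a, b, ww) {
    adj[[a]] <<- c(adj[[a]], b)
    if (!is.null(w)) wts[[a]] <<- c(wts[[a]], ww)
  }
  for (i in seq_len(nrow(el))) {
    add(el[i, 1L], el[i, 2L], if (is.null(w)) 1 else w[i])
    if (!igraph::is_directed(g))
      add(el[i, 2L], el[i, 1L], if (is.null(w)) 1 else w[i])
  }
  for (v in seq_len(n)) if (is.null(adj[[v]])) adj[[v]] <- integer(0)
  list(adj = adj, wts = wts)
}

# Brandes dependency accumulation; kind = "betweenness" accumulates
# sigma-fraction dependencies, "stress" accumulates raw geodesic counts
brandes_accumulate <- function(g, kind) {
  n <- igraph::vcount(g)
  oa <- out_adjacency(g)
  score <- numeric(n)
  for (s in seq_len(n)) {
    sp <- sssp(oa$adj, oa$wts, s, n)
    if (kind == "betweenness") {
      delta <- numeric(n)
      for (w in rev(sp$order)) {
        for (v in sp$preds[[w]])
          delta[v] <- delta[v] + sp$sigma[v] / sp$sigma[w] * (1 + delta[w])
        if (w != s) score[w] <- score[w] + delta[w]
      }
    } else {
      # psi[v] = number of geodesic-DAG paths from v to any target below it
      psi <- numeric(n)
      for (w in rev(sp$order)) {
        for (v in sp$preds[[w]]) psi[v] <- psi[v] + psi[w] + 1
        if (w != s) score[w] <- score[w] + sp$sigma[w] * psi[w]
      }
    }
  }
  if (!igraph::is_directed(g)) score / 2 else score
}

# Newman-Goh load: unit packets split equally among geodesic predecessors
load_accumulate <- function(g) {
  n <- igraph::vcount(g)
  oa <- out_adjacency(g)
  score <- numeric(n)
  for (s in seq_len(n)) {
    sp <- sssp(oa$adj, oa$wts, s, n)
    c_amt <- numeric(n)
    reach <- sp$order[sp$order != s]
    c_amt[reach] <- 1
    for (w in rev(sp$order)) {
      np <- length(sp$preds[[w]])
      if (np == 0) next
      share <- c_amt[w] / np
      for (v in sp$preds[[w]]) {
        c_amt[v] <- c_amt[v] + share
        if (v != s) score[v] <- score[v] + share
      }
    }
  }
  if (!igraph::is_directed(g)) score / 2 else score
}

# Freeman flow betweenness: flow forced through v, as the drop in s-t
# max-flow when v is removed, summed over pairs as a fraction of max-flow
flow_betweenness_raw <- function(g) {
  n <- igraph::vcount(g)
  directed <- igraph::is_directed(g)
  cap <- if (is_weighted_graph(g)) igraph::E(g)$weight else rep(1, igraph::ecount(g))
  pairs <- if (directed) {
    as.matrix(expand.grid(s = seq_len(n), t = seq_len(n)))
  } else t(utils::combn(n, 2L))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  F0 <- apply(pairs, 1L, function(p)
    igraph::max_flow(g, p[1L], p[2L], capacity = cap)$value)
  score <- numeric(n)
  for (v in seq_len(n)) {
    keep <- pairs[, 1L] != v & pairs[, 2L] != v & F0 > 0
    if (!any(keep)) next
    gv <- igraph::delete_vertices(g, v)
    capv <- if (is_weighted_graph(gv)) igraph::E(gv)$weight else
      rep(1, igraph::ecount(gv))
    old2new <- cumsum(seq_len(n) != v) # vertex ids after deletion
    pk <- pairs[keep, , drop = FALSE]
    Fv <- vapply(seq_len(nrow(pk)), function(i)
      igraph::max_flow(gv, old2new[pk[i, 1L]], old2new[pk[i, 2L]],
                       capacity = capv)$value, 0)
    score[v] <- sum((F0[keep] - Fv) / F0[keep])
  }
  score
}

# Laplacian pseudoinverse of one connected component (conductance weights)
component_lplus <- function(g, verts) {
  sub <- igraph::induced_subgraph(g, verts)
  A <- adjacency_of(sub)
  L <- diag(rowSums(A), nrow(A)) - A
  nc <- nrow(A)
  solve(L + 1 / nc) - 1 / nc
}

cfb_raw <- function(g) {
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  score <- numeric(n)
  for (ci in seq_len(comp$no)) {
    verts <- which(comp$membership == ci)
    nc <- length(verts)
    if (nc < 3) next
    Lp <- component_lplus(g, verts)
    A <- adjacency_of(igraph::induced_subgraph(g, verts))
    for (si in seq_len(nc - 1L)) for (ti in seq.int(si + 1L, nc)) {
      p <- Lp[, si] - Lp[, ti]
      thr <- 0.5 * rowSums(A * abs(outer(p, p, "-")))
      thr[c(si, ti)] <- 0
      score[verts] <- score[verts] + thr
    }
  }
  score
}

cfc_raw <- function(g) {
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  if (comp$no > 1)
    message("current_flow_closeness computed per connected component")
  score <- numeric(n)
  for (ci in seq_len(comp$no)) {
    verts <- which(comp$membership == ci)
    nc <- length(verts)
    if (nc == 1) { score[verts] <- 0; next }
    Lp <- component_lplus(g, verts)
    d <- diag(Lp)
    # sum_u effective resistance v-u = nc * Lp_vv + trace(Lp)
    score[verts] <- (nc - 1) / (nc * d + sum(d))
  }
  score
}

information_raw <- function(g) {
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  if (comp$no > 1)
    message("information centrality computed per connected component")
  score <- numeric(n)
  for (ci in seq_len(comp$no)) {
    verts <- which(comp$membership == ci)
    nc <- length(verts)
    if (nc == 1) { score[verts] <- 0; next }
    A <- adjacency_of(igraph::induced_subgraph(g, verts))
    L <- diag(rowSums(A), nc) - A
    C <- solve(L + 1)
    d <- diag(C)
    denom <- vapply(seq_len(nc), function(v)
      sum(d[v] + d[-v] - 2 * C[v, -v]), 0)
    score[verts] <- (nc - 1) / denom
  }
  score
}

comm_betweenness_raw <- function(g) {
  n <- igraph::vcount(g)
  A <- adjacency_of(g)
  G0 <- expm_sym(A)
  Cnorm <- (n - 1)^2 - (n - 1)
  score <- numeric(n)
  for (v in seq_len(n)) {
    Av <- A; Av[v, ] <- 0; Av[, v] <- 0
    Gv <- expm_sym(Av)
    W <- (G0 - Gv) / G0
    W[v, ] <- 0; W[, v] <- 0; diag(W) <- 0
    score[v] <- sum(W) / Cnorm
  }
  score
}

expm_sym <- function(A) {
  ed <- eigen(A, symmetric = TRUE)
  ed$vectors %*% (exp(ed$values) * t(ed$vectors))
}

# Markov centrality from mean first-passage times of the simple random
# walk (weighted: transition proportional to edge weight), per strongly
# connected component
markov_raw <- function(g) {
  n <- igraph::vcount(g)
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1)
    warning("markov centrality computed per strongly connected component")
  score <- numeric(n)
  for (ci in seq_len(comp$no)) {
    verts <- which(comp$membership == ci)
    nc <- length(verts)
    if (nc == 1) { score[verts] <- 0; next }
    sub <- igraph::induced_subgraph(g, verts)
    A <- adjacency_of(sub)
    P <- A / rowSums(A)
    M <- mfpt_matrix(P)
    score[verts] <- nc / colSums(M)
  }
  score
}

# mean first-passage matrix via the fundamental matrix Z; M[u, v] is the
# expected steps from u to v, M[v, v] = 0
mfpt_matrix <- function(P) {
  nc <- nrow(P)
  pi0 <- stationary_dist(P)
  Z <- solve(diag(nc) - P + matrix(pi0, nc, nc, byrow = TRUE))
  M <- matrix(0, nc, nc)
  for (v in seq_len(nc)) M[, v] <- (Z[v, v] - Z[, v]) / pi0[v]
  M
}

stationary_dist <- function(P) {
  nc <- nrow(P)
  a <- rbind(t(diag(nc) - P), rep(1, nc))
  qr.solve(a, c(rep(0, nc), 1))
}
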