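#' Feedback (matrix / spectral) centrality family
#'
#' Measures defined through the adjacency matrix \eqn{A} (weights read as
#' connection strengths, not distances): eigenvector centrality, Katz
#' status index, alpha centrality, Bonacich power, Hubbell index,
#' PageRank, LeaderRank, HITS, SALSA, subgraph centrality, Laplacian
#' centrality, entropy (path-transfer) centrality and community
#' centrality.
#'
#' Defaults that depend on the spectrum are resolved at call time:
#' \code{katz}/\code{alpha_centrality} use \eqn{\alpha = 0.5/\lambda_{max}},
#' \code{bonacich_power} uses \eqn{\beta = 0.9/\lambda_{max}} and
#' \code{hubbell} scales \eqn{A^T} by \eqn{0.5/\lambda_{max}}, which
#' guarantees the defining linear systems are invertible.  Power
#' iterations start from the uniform vector (no randomness).
#'
#' @param g labelled igraph object, already simplified.
#' @param measure_id one of the family ids (see
#'   \code{list_measures("feedback")}).
#' @param params list; see [list_measures()] for per-measure entries
#'   (\code{alpha}, \code{beta}, \code{exo}, \code{damping}, \code{tol},
#'   \code{max_iter}, \code{weight_factor}, \code{samples},
#'   \code{exact_limit}, \code{seed}).
#' @return a [score_vector]; \code{hits} exposes hub scores in
#'   \code{$extra$hub}, \code{community} the leading-eigenvalue basis in
#'   \code{$extra}.
#' @examples
#' s5 <- make_fixture(fixture_spec("star", n = 5))
#' feedback_score(s5, "eigenvector")$scores
#' @export
feedback_score <- function(g, measure_id, params = list()) {
  desc <- measure_descriptor(measure_id)
  if (desc$family != "feedback")
    stop("'", measure_id, "' is not in the feedback family")
  pars <- resolve_params(desc, params)
  labs <- vertex_labels(g)
  n <- length(labs)
  A <- adjacency_of(g)
  lam <- spectral_radius(A)
  I <- diag(n)
  ones <- rep(1, n)
  named <- function(x) stats::setNames(as.numeric(x), labs)
  extra <- NULL

  scores <- switch(measure_id,
    eigenvector = {
      if (igraph::ecount(g) == 0) named(rep(0, n)) else {
        x <- principal_eigvec(if (igraph::is_directed(g)) t(A) else A)
        named(x / max(x))
      }
    },
    katz = {
      a <- resolve_alpha(pars$alpha, lam, 0.5, "katz")
      named(solve(I - a * t(A), a * t(A) %*% ones))
    },
    alpha_centrality = {
      a <- resolve_alpha(pars$alpha, lam, 0.5, "alpha_centrality")
      named(solve(I - a * t(A), rep_len(pars$exo, n)))
    },
    bonacich_power = {
      b <- if (is.na(pars$beta)) (if (lam > 0) 0.9 / lam else 0.9) else pars$beta
      if (abs(b) * lam >= 1)
        stop("bonacich_power diverges: |beta| >= 1/lambda_max = ",
             format(1 / lam))
      named(pars$alpha * solve(I - b * A, A %*% ones))
    },
    hubbell = {
      w <- if (is.na(pars$weight_factor))
        (if (lam > 0) 0.5 / lam else 0.5) else pars$weight_factor
      W <- w * t(A)
      if (spectral_radius(W) >= 1)
        stop("hubbell diverges: scaled matrix has spectral radius >= 1")
      named(solve(I - W, rep_len(pars$exo, n)))
    },
    pagerank = named(pagerank_vec(A, pars$damping, pars$tol, pars$max_iter)),
    leaderrank = named(leaderrank_vec(g, pars$tol, pars$max_iter)),
    hits = {
      hh <- hits_vecs(A, pars$tol, pars$max_iter)
      extra <- list(hub = stats::setNames(hh$hub, labs))
      named(hh$authority)
    },
    salsa = named(salsa_authority(g, pars$tol, pars$max_iter)),
    subgraph = {
      ed <- eigen(A, symmetric = TRUE)
      named(rowSums(ed$vectors^2 %*% diag(exp(ed$values), n)))
    },
    laplacian = {
      s <- rowSums(A)
      named(vapply(seq_len(n), function(v)
        s[v]^2 + sum(2 * s[-v] * A[-v, v] + A[-v, v]^2), 0))
    },
    entropy = named(entropy_centrality_vec(g, pars$samples,
                                           pars$exact_limit, pars$seed)),
    community = {
      m2 <- sum(A)
      if (m2 == 0) named(rep(0, n)) else {
        k <- rowSums(A)
        B <- A - outer(k, k) / m2
        ed <- eigen(B, symmetric = TRUE)
        pos <- ed$values > 1e-12
        if (!any(pos)) named(rep(0, n)) else
          named(sqrt(rowSums(
            (ed$vectors[, pos, drop = FALSE]^2) %*%
              diag(ed$values[pos], sum(pos)))))
      }
    },
    stop("unhandled feedback measure '", measure_id, "'"))
  score_vector(measure_id, scores, pars, extra = extra)
}

spectral_radius <- function(A) {
  if (!nrow(A)) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

resolve_alpha <- function(alpha, lam, frac, what) {
  a <- if (is.na(alpha)) (if (lam > 0) frac / lam else frac) else alpha
  if (lam > 0 && a >= 1 / lam)
    stop(what, " diverges: alpha >= 1/lambda_max = ", format(1 / lam))
  a
}

principal_eigvec <- function(M) {
  if (isSymmetric(unname(M))) {
    ed <- eigen(M, symmetric = TRUE)
    v <- ed$vectors[, which.max(ed$values)]
  } else {
    ed <- eigen(M)
    v <- Re(ed$vectors[, which.max(Re(ed$values))])
  }
  abs(v)
}

pagerank_vec <- function(A, damping, tol, max_iter) {
  n <- nrow(A)
  out <- rowSums(A)
  P <- A / ifelse(out == 0, 1, out)
  dangling <- out == 0
  x <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    xn <- damping * (crossprod(P, x) + sum(x[dangling]) / n) +
      (1 - damping) / n
    xn <- as.numeric(xn)
    if (sum(abs(xn - x)) < tol) return(xn / sum(xn))
    x <- xn
  }
  stop("pagerank did not converge after ", max_iter,
       " iterations (residual ", format(sum(abs(xn - x))), ")")
}

# ground vertex bidirectionally linked to every vertex; score folds the
# ground's mass back uniformly
leaderrank_vec <- function(g, tol, max_iter) {
  n <- igraph::vcount(g)
  A <- adjacency_of(g, use_weights = FALSE)
  Ag <- rbind(cbind(A, 1), c(rep(1, n), 0))
  out <- rowSums(Ag)
  P <- Ag / out
  s <- c(rep(1, n), 0)
  for (i in seq_len(max_iter)) {
    sn <- as.numeric(crossprod(P, s))
    if (sum(abs(sn - s)) < tol) return(sn[1:n] + sn[n + 1] / n)
    s <- sn
  }
  stop("leaderrank did not converge after ", max_iter, " iterations",
       " (residual ", format(sum(abs(sn - s))), ")")
}

hits_vecs <- function(A, tol, max_iter) {
  n <- nrow(A)
  h <- rep(1 / sqrt(n), n)
  a <- h
  for (i in seq_len(max_iter)) {
    an <- as.numeric(crossprod(A, h)); an <- an / norm2(an)
    hn <- as.numeric(A %*% an);        hn <- hn / norm2(hn)
    if (sum(abs(an - a)) + sum(abs(hn - h)) < tol)
      return(list(authority = an, hub = hn))
    a <- an; h <- hn
  }
  stop("hits did not converge after ", max_iter, " iterations")
}

norm2 <- function(x) { s <- sqrt(sum(x^2)); if (s == 0) 1 else s }

# authority-side stationary distribution of the alternating (hub ->
# authority) walk, per connected component of the bipartite expansion,
# each component weighted by its share of the arcs
salsa_authority <- function(g, tol, max_iter) {
  n <- igraph::vcount(g)
  A <- adjacency_of(g, use_weights = FALSE)
  if (!igraph::is_directed(g)) A <- pmax(A, t(A))  # each edge as two arcs
  din <- colSums(A); dout <- rowSums(A)
  m <- sum(A)
  score <- rep(0, n)
  if (m == 0) return(score)
  Ac <- t(t(A) / ifelse(din == 0, 1, din))  # column-normalised
  Ar <- A / ifelse(dout == 0, 1, dout)      # row-normalised
  Tmat <- crossprod(Ac, Ar)                 # authority -> authority
  # bipartite expansion: hub copy i, authority copy n + j, arcs i -> n+j
  idx <- which(A > 0, arr.ind = TRUE)
  bg <- igraph::add_edges(igraph::make_empty_graph(2L * n, directed = FALSE),
                          rbind(idx[, 1L], n + idx[, 2L]))
  comp <- igraph::components(bg)$membership
  for (ci in unique(comp[n + which(din > 0)])) {
    auth <- which(din > 0 & comp[n + seq_len(n)] == ci)
    arcs <- sum(A[, auth])
    x <- rep(1 / length(auth), length(auth))
    Tc <- Tmat[auth, auth, drop = FALSE]
    ok <- FALSE
    for (i in seq_len(max_iter)) {
      xn <- as.numeric(crossprod(Tc, x))
      xn <- xn / sum(xn)
      if (sum(abs(xn - x)) < tol) { ok <- TRUE; x <- xn; break }
      x <- xn
    }
    if (!ok) stop("salsa did not converge after ", max_iter, " iterations")
    score[auth] <- x * arcs / m
  }
  score
}

# Path-transfer (Tutzauer) entropy: a unit of flow starts at v and moves
# to a uniformly chosen not-yet-visited neighbor until stuck; tau_vu is
# the probability it stops at u.  Exact by path enumeration on small
# graphs, seeded Monte Carlo above `exact_limit` vertices.
entropy_centrality_vec <- function(g, samples, exact_limit, seed) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v)
    as.integer(igraph::neighbors(g, v, mode = "out")))
  one_vertex_exact <- function(v) {
    tau <- numeric(n)
    rec <- function(cur, visited, p) {
      nxt <- setdiff(adj[[cur]], visited)
      if (!length(nxt)) { tau[cur] <<- tau[cur] + p; return() }
      for (u in nxt) rec(u, c(visited, u), p / length(nxt))
    }
    rec(v, v, 1)
    tau
  }
  one_vertex_mc <- function(v) {
    tau <- numeric(n)
    for (s in seq_len(samples)) {
      cur <- v; visited <- logical(n); visited[v] <- TRUE
      repeat {
        nxt <- adj[[cur]]; nxt <- nxt[!visited[nxt]]
        if (!length(nxt)) break
        cur <- if (length(nxt) == 1L) nxt else nxt[sample.int(length(nxt), 1L)]
        visited[cur] <- TRUE
      }
      tau[cur] <- tau[cur] + 1
    }
    tau / samples
  }
  ent <- function(tau) { p <- tau[tau > 0]; -sum(p * log2(p)) }
  if (n <= exact_limit) {
    vapply(seq_len(n), function(v) ent(one_vertex_exact(v)), 0)
  } else {
    with_seed(seed, vapply(seq_len(n), function(v) ent(one_vertex_mc(v)), 0))
  }
}
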