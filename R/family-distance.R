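#' Geodesic-distance centrality family
#'
#' Measures derived from the shortest-path distance matrix: the Freeman,
#' Latora (harmonic) and Dangalchev closeness variants, barycenter, Lin,
#' eccentricity, radiality, centroid value, decay, average distance,
#' closeness vitality and geodesic K-path.  On weighted graphs edge
#' weights are interpreted as distances; on directed graphs out-distances
#' are used.
#'
#' Disconnection handling: formulas are evaluated over the reachable set
#' \eqn{R(v)} (vertices at finite distance, excluding \eqn{v}).  Freeman
#' closeness carries the penalty factor \eqn{|R(v)|/(n-1)} so scores stay
#' comparable across components.  A vertex with empty \eqn{R(v)} scores 0
#' (with a warning) for the measures whose formula would otherwise divide
#' by zero.
#'
#' @param g labelled igraph object, already simplified.
#' @param measure_id one of the family ids (see
#'   \code{list_measures("distance")}).
#' @param params list; \code{delta} in (0,1) for \code{decay} (default
#'   0.5), positive integer \code{k} for \code{geodesic_kpath} (default 3).
#' @return a [score_vector].
#' @examples
#' p3 <- make_fixture(fixture_spec("path", n = 3))
#' distance_score(p3, "closeness_latora")$scores
#' @export
distance_score <- function(g, measure_id, params = list()) {
  desc <- measure_descriptor(measure_id)
  if (desc$family != "distance")
    stop("'", measure_id, "' is not in the distance family")
  pars <- resolve_params(desc, params)
  labs <- vertex_labels(g)
  n <- length(labs)
  D <- distances_of(g, mode = "out")
  diag(D) <- Inf  # exclude v from its own reachable set uniformly
  fin <- is.finite(D)
  diam <- if (any(fin)) max(D[fin]) else 0

  per_vertex <- function(f) stats::setNames(vapply(seq_len(n), f, 0), labs)
  warn_isolated <- function(r) {
    if (any(r == 0))
      warning("vertex with empty reachable set: score set to 0 for '",
              measure_id, "'")
  }
  rr <- rowSums(fin)                     # |R(v)|
  ss <- rowSums(ifelse(fin, D, 0))       # sum of finite distances

  scores <- switch(measure_id,
    closeness_freeman = {
      s <- ifelse(rr > 0, (rr / pmax(ss, .Machine$double.xmin)) *
                    (rr / max(n - 1, 1)), 0)
      stats::setNames(s, labs)
    },
    closeness_latora = stats::setNames(rowSums(ifelse(fin, 1 / D, 0)), labs),
    closeness_dangalchev =
      stats::setNames(rowSums(ifelse(fin, 2^(-D), 0)), labs),
    barycenter = {
      warn_isolated(rr)
      stats::setNames(ifelse(rr > 0, 1 / ss, 0), labs)
    },
    lin = {
      warn_isolated(rr)
      stats::setNames(ifelse(rr > 0, (rr + 1)^2 / ss, 0), labs)
    },
    eccentricity = {
      warn_isolated(rr)
      per_vertex(function(v)
        if (rr[v] > 0) 1 / max(D[v, fin[v, ]]) else 0)
    },
    radiality = {
      s <- rowSums(ifelse(fin, diam + 1 - D, 0)) / max(n - 1, 1)
      stats::setNames(s, labs)
    },
    decay = {
      delta <- pars$delta
      stats::setNames(rowSums(ifelse(fin, delta^D, 0)), labs)
    },
    average_distance = {
      warn_isolated(rr)
      stats::setNames(ifelse(rr > 0, ss / rr, 0), labs)
    },
    closeness_vitality = {
      W <- wiener_index(g)
      per_vertex(function(v)
        W - wiener_index(igraph::delete_vertices(g, v)))
    },
    geodesic_kpath = {
      k <- pars$k
      stats::setNames(rowSums(fin & D <= k), labs)
    },
    centroid_value = {
      # gamma[v, w] = #{u not in {v,w} : d(u,v) < d(u,w)}, distances INTO v
      per_vertex(function(v) {
        f <- vapply(seq_len(n), function(w) {
          if (w == v) return(NA_real_)
          u <- setdiff(seq_len(n), c(v, w))
          duv <- D[u, v]; duw <- D[u, w]
          sum(duv < duw) - sum(duw < duv)
        }, 0)
        min(f, na.rm = TRUE)
      })
    },
    stop("unhandled distance measure '", measure_id, "'"))
  score_vector(measure_id, scores, pars)
}

#' Wiener index
#'
#' Sum of finite shortest-path distances over vertex pairs: each unordered
#' pair once on undirected graphs, each ordered pair once on directed
#' graphs.  Infinite (disconnected) pairs contribute nothing.
#'
#' @param g labelled igraph object.
#' @return a single number.
#' @export
wiener_index <- function(g) {
  if (igraph::vcount(g) < 2L) return(0)
  D <- distances_of(g, mode = "out")
  diag(D) <- Inf
  tot <- sum(D[is.finite(D)])
  if (igraph::is_directed(g)) tot else tot / 2
}
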