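#' Local neighborhood centrality family
#'
#' Degree-type and neighborhood-structure measures: degree, strength,
#' lobby index, leverage, local clustering coefficient, topological
#' coefficient, k-core decomposition, semi-local centrality, ClusterRank,
#' diffusion degree, MNC/DMNC (maximum neighborhood component and its
#' density), cross-clique connectivity, Burt's constraint and graphlet
#' degree.
#'
#' @param g labelled igraph object, already simplified.
#' @param measure_id one of the family ids (see
#'   \code{list_measures("neighborhood")}).
#' @param params list; relevant entries: \code{mode} for degree/strength
#'   (\code{"total"}, \code{"in"}, \code{"out"}), \code{lambda} for
#'   diffusion degree (default 1), \code{epsilon} in (1,2) for DMNC
#'   (default 1.7), \code{max_size} in \{3,4\} for graphlet degree
#'   (default 4).
#' @return a [score_vector]; graphlet degree additionally exposes the full
#'   per-vertex orbit count matrix in \code{$extra$orbits}.
#' @examples
#' s5 <- make_fixture(fixture_spec("star", n = 5))
#' neighborhood_score(s5, "leverage")$scores
#' @export
neighborhood_score <- function(g, measure_id, params = list()) {
  desc <- measure_descriptor(measure_id)
  if (desc$family != "neighborhood")
    stop("'", measure_id, "' is not in the neighborhood family")
  pars <- resolve_params(desc, params)
  labs <- vertex_labels(g)
  n <- length(labs)
  deg <- igraph::degree(g, mode = "all")
  nbrs <- lapply(seq_len(n), function(v)
    as.integer(igraph::neighbors(g, v, mode = "all")))
  per_vertex <- function(f) stats::setNames(vapply(seq_len(n), f, 0), labs)
  extra <- NULL

  scores <- switch(measure_id,
    degree = stats::setNames(
      as.numeric(igraph::degree(g, mode = deg_mode(pars$mode))), labs),
    strength = stats::setNames(
      as.numeric(igraph::strength(g, mode = deg_mode(pars$mode))), labs),
    lobby = per_vertex(function(v) {
      nd <- sort(deg[nbrs[[v]]], decreasing = TRUE)
      sum(nd >= seq_along(nd))
    }),
    leverage = {
      if (any(deg == 0))
        warning("leverage of an isolated vertex set to 0")
      per_vertex(function(v) {
        if (deg[v] == 0) return(0)
        ku <- deg[nbrs[[v]]]
        mean((deg[v] - ku) / (deg[v] + ku))
      })
    },
    local_clustering = stats::setNames(
      igraph::transitivity(g, type = "localundirected", isolates = "zero"),
      labs),
    topological_coefficient = per_vertex(function(v) {
      if (deg[v] == 0) return(0)
      nv <- nbrs[[v]]
      shared <- vapply(setdiff(seq_len(n), v), function(u) {
        j <- length(intersect(nv, nbrs[[u]]))
        if (j == 0) return(NA_real_)
        j + (u %in% nv)
      }, 0)
      shared <- shared[!is.na(shared)]
      if (!length(shared)) 0 else mean(shared) / deg[v]
    }),
    kcore = stats::setNames(as.numeric(igraph::coreness(g)), labs),
    semilocal = {
      n2 <- igraph::ego_size(g, order = 2, mindist = 1)
      q <- vapply(seq_len(n), function(u) sum(n2[nbrs[[u]]]), 0)
      per_vertex(function(v) sum(q[nbrs[[v]]]))
    },
    clusterrank = {
      cc <- igraph::transitivity(
        igraph::as_undirected(g, mode = "collapse"),
        type = "localundirected", isolates = "zero")
      dird <- igraph::is_directed(g)
      kout <- igraph::degree(g, mode = if (dird) "out" else "all")
      per_vertex(function(v) {
        nb <- as.integer(igraph::neighbors(g, v,
                                           mode = if (dird) "out" else "all"))
        10^(-cc[v]) * sum(kout[nb] + 1)
      })
    },
    diffusion_degree = per_vertex(function(v)
      pars$lambda * deg[v] + pars$lambda * sum(deg[nbrs[[v]]])),
    mnc = per_vertex(function(v) max_nbr_component(g, nbrs[[v]])$size),
    dmnc = per_vertex(function(v) {
      m <- max_nbr_component(g, nbrs[[v]])
      if (m$size <= 1) 0 else m$edges / m$size^pars$epsilon
    }),
    cross_clique = {
      ncl <- igraph::count_max_cliques(g)
      if (ncl > 5e5)
        stop("graph has ", ncl, " maximal cliques; ",
             "cross-clique connectivity refused above 5e5")
      cl <- igraph::max_cliques(g)
      cnt <- tabulate(unlist(lapply(cl, as.integer)), nbins = n)
      stats::setNames(as.numeric(cnt), labs)
    },
    burt_constraint = burt_constraint_scores(g, labs),
    graphlet_degree = {
      orb <- graphlet_orbit_counts(g, max_size = pars$max_size)
      extra <- list(orbits = orb)
      stats::setNames(rowSums(orb), labs)
    },
    stop("unhandled neighborhood measure '", measure_id, "'"))
  score_vector(measure_id, scores, pars, extra = extra)
}

deg_mode <- function(mode) switch(mode, total = "all", mode)

# largest connected component of the open-neighborhood induced subgraph
max_nbr_component <- function(g, nv) {
  if (length(nv) == 0) return(list(size = 0, edges = 0))
  sub <- igraph::induced_subgraph(g, nv)
  comp <- igraph::components(sub)
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  # size ties broken toward the denser component (deterministic)
  edges <- max(vapply(cand, function(ci) igraph::ecount(
    igraph::induced_subgraph(sub, which(comp$membership == ci))), 0))
  list(size = best_size, edges = edges)
}

# Burt's constraint: c_v = sum_{j in N(v)} (p_vj + sum_q p_vq p_qj)^2,
# p = adjacency (weights as tie strength) normalised by row sums
burt_constraint_scores <- function(g, labs) {
  A <- adjacency_of(g)
  A <- A + t(A); A <- A / 2            # symmetrise tie strengths
  rs <- rowSums(A)
  if (any(rs == 0))
    warning("Burt's constraint of an isolated vertex set to 0")
  P <- A / ifelse(rs == 0, 1, rs)
  val <- P + P %*% P
  cons <- rowSums((val * (A > 0))^2)
  stats::setNames(ifelse(rs == 0, 0, cons), labs)
}
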