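#' Perturbation / percolation centrality family
#'
#' Measures that score a vertex by what its removal (or random edge
#' failure) does to the network: bottleneck, bridging centrality, the
#' edge-percolated component (EPC) and the pairwise disconnectivity
#' index.
#'
#' @param g labelled igraph object, already simplified.
#' @param measure_id one of the family ids (see
#'   \code{list_measures("perturbation")}).
#' @param params list; for \code{epc}: \code{retention} in (0, 1]
#'   (default 0.5), \code{samples} (default 1000) and \code{seed}
#'   (default 1) for the Monte Carlo edge-retention draws.
#' @return a [score_vector].
#' @examples
#' p3 <- make_fixture(fixture_spec("path", n = 3))
#' perturbation_score(p3, "pairwise_disconnectivity")$scores
#' @export
perturbation_score <- function(g, measure_id, params = list()) {
  desc <- measure_descriptor(measure_id)
  if (desc$family != "perturbation")
    stop("'", measure_id, "' is not in the perturbation family")
  pars <- resolve_params(desc, params)
  labs <- vertex_labels(g)
  n <- length(labs)
  named <- function(x) stats::setNames(as.numeric(x), labs)

  scores <- switch(measure_id,
    bottleneck = named(bottleneck_raw(g)),
    bridging = {
      btw <- brandes_accumulate(g, kind = "betweenness")
      deg <- igraph::degree(g, mode = "all")
      if (any(deg == 0))
        warning("bridging coefficient of an isolated vertex set to 0")
      bc <- vapply(seq_len(n), function(v) {
        if (deg[v] == 0) return(0)
        nb <- as.integer(igraph::neighbors(g, v, mode = "all"))
        (1 / deg[v]) / sum(1 / deg[nb])
      }, 0)
      named(btw * bc)
    },
    epc = {
      if (pars$retention <= 0)
        stop("epc retention probability must be in (0, 1]")
      named(epc_raw(g, pars$retention, pars$samples, pars$seed))
    },
    pairwise_disconnectivity = named(pairwise_disconnectivity_raw(g)),
    stop("unhandled perturbation measure '", measure_id, "'"))
  score_vector(measure_id, scores, pars)
}

# one deterministic BFS tree per root (parent = first-seen neighbor in
# vertex order); a vertex scores 1 per root whose tree routes more than a
# quarter of the tree's paths through it as an interior vertex
bottleneck_raw <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v)
    sort(as.integer(igraph::neighbors(g, v, mode = "out"))))
  score <- numeric(n)
  for (s in seq_len(n)) {
    parent <- rep(NA_integer_, n)
    seen <- logical(n); seen[s] <- TRUE
    queue <- s; tree <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- v
        queue <- c(queue, w); tree <- c(tree, w)
      }
    }
    tsize <- length(tree)
    if (tsize < 2L) next
    # subtree sizes by processing discovery order backwards
    sub <- rep(1L, n)
    for (w in rev(tree)) if (!is.na(parent[w]))
      sub[parent[w]] <- sub[parent[w]] + sub[w]
    interior <- setdiff(tree, s)
    hit <- interior[(sub[interior] - 1L) > tsize / 4]
    score[hit] <- score[hit] + 1
  }
  score
}

# mean size of the percolated component containing v (v counts itself)
# over seeded random edge-retention realizations
epc_raw <- function(g, retention, samples, seed) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  with_seed(seed, {
    acc <- numeric(n)
    for (b in seq_len(samples)) {
      drop <- which(stats::runif(m) > retention)
      gs <- if (length(drop)) igraph::delete_edges(g, drop) else g
      comp <- igraph::components(gs)
      acc <- acc + comp$csize[comp$membership]
    }
    acc / samples
  })
}

pairwise_disconnectivity_raw <- function(g) {
  n <- igraph::vcount(g)
  reach_pairs <- function(h) {
    D <- igraph::distances(h, mode = "out", weights = NA)
    diag(D) <- Inf
    sum(is.finite(D))
  }
  n0 <- reach_pairs(g)
  if (n0 == 0) stop("pairwise disconnectivity undefined: no connected pairs")
  vapply(seq_len(n), function(v)
    (n0 - reach_pairs(igraph::delete_vertices(g, v))) / n0, 0)
}
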