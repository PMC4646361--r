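#' Graphlet orbit counts
#'
#' Counts, for every vertex, the automorphism orbits of the connected
#' induced subgraphs (graphlets) on 2-4 vertices it participates in,
#' using the standard orbit numbering: orbit 0 (edge), orbits 1-2 (path
#' P3), 3 (triangle), 4-5 (path P4), 6-7 (claw K1,3), 8 (cycle C4),
#' 9-11 (paw), 12-13 (diamond), 14 (complete K4).  Enumeration walks the
#' subgraph-extension tree (ESU), so each connected induced subgraph is
#' visited exactly once.
#'
#' @param g labelled igraph object (undirected, simple).
#' @param max_size 3 or 4: largest graphlet size counted.
#' @return integer matrix, one row per vertex, one column per orbit
#'   (\code{o0} ... \code{o14}; orbit columns above \code{max_size}
#'   graphlets are absent).
#' @export
graphlet_orbit_counts <- function(g, max_size = 4) {
  stopifnot(max_size %in% c(3, 4))
  n <- igraph::vcount(g)
  n_orb <- if (max_size == 3) 4L else 15L
  counts <- matrix(0L, n, n_orb,
                   dimnames = list(vertex_labels(g),
                                   paste0("o", seq_len(n_orb) - 1L)))
  adj <- lapply(seq_len(n), function(v)
    as.integer(igraph::neighbors(g, v)))
  A <- lapply(seq_len(n), function(v) {
    z <- logical(n); z[adj[[v]]] <- TRUE; z
  })
  record <- function(S) {
    k <- length(S)
    if (k < 2L) return()
    din <- vapply(S, function(v) sum(A[[v]][S]), 0L)
    orb <- classify_orbits(k, din)
    if (is.null(orb)) return()
    for (i in seq_len(k))
      counts[S[i], orb[i] + 1L] <<- counts[S[i], orb[i] + 1L] + 1L
  }
  # ESU: extend only with vertices > root, not already in the extension set
  extend <- function(S, ext, root) {
    record(S)
    if (length(S) == max_size || !length(ext)) return()
    while (length(ext)) {
      w <- ext[1L]; ext <- ext[-1L]
      excl <- unique(unlist(lapply(S, function(v) adj[[v]])))
      new_ext <- c(ext, setdiff(adj[[w]][adj[[w]] > root],
                                c(excl, S, w)))
      extend(c(S, w), new_ext, root)
    }
  }
  for (v in seq_len(n))
    extend(v, adj[[v]][adj[[v]] > v], v)
  counts
}

# orbit of each vertex of a connected graphlet on k vertices, given the
# within-graphlet degree sequence; NULL when the subgraph is disconnected
# (cannot happen under ESU, kept as a guard for direct calls)
classify_orbits <- function(k, din) {
  e <- sum(din) / 2
  if (k == 2L) return(rep(0L, 2L))
  if (k == 3L) {
    if (e == 2) return(ifelse(din == 2L, 2L, 1L))   # P3: mid 2, ends 1
    if (e == 3) return(rep(3L, 3L))                 # triangle
    return(NULL)
  }
  if (e == 3) {                                     # P4 or claw
    if (max(din) == 3L) return(ifelse(din == 3L, 7L, 6L))
    return(ifelse(din == 2L, 5L, 4L))
  }
  if (e == 4) {                                     # C4 or paw
    if (max(din) == 2L) return(rep(8L, 4L))
    out <- integer(4L)
    out[din == 1L] <- 9L; out[din == 2L] <- 10L; out[din == 3L] <- 11L
    return(out)
  }
  if (e == 5) return(ifelse(din == 3L, 13L, 12L))   # diamond
  if (e == 6) return(rep(14L, 4L))                  # K4
  NULL
}
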