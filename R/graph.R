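#' Build a centrality-ready network
#'
#' All measures in this package operate on an \pkg{igraph} graph whose
#' vertices carry unique character labels in the \code{name} attribute and
#' whose edges, when the graph is weighted, carry strictly positive weights
#' in the \code{weight} attribute.  \code{as_netgraph()} normalises an edge
#' table or an igraph object into that form and (optionally) simplifies it.
#'
#' @param x a two- or three-column data frame / matrix (source, target,
#'   optional weight) or an igraph object.
#' @param directed logical; interpret edges as arcs.
#' @param weighted logical; keep the third column / \code{weight} attribute.
#'   When \code{FALSE} any weights present are dropped with a warning and
#'   every edge gets weight 1.
#' @param simplify logical; remove self-loops and duplicate edges
#'   (duplicate = same unordered pair when undirected, same ordered pair
#'   when directed).  Weights of collapsed duplicates keep the first value.
#' @param vertices optional character vector of labels fixing vertex order;
#'   defaults to first appearance order in the edge table.
#' @return an igraph object satisfying [validate_netgraph()].
#' @export
as_netgraph <- function(x, directed = FALSE, weighted = FALSE,
                        simplify = TRUE, vertices = NULL) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    if (igraph::is_directed(g) != directed)
      g <- if (directed) igraph::as_directed(g, mode = "arbitrary")
           else igraph::as_undirected(g, mode = "each",
                                      edge.attr.comb = list(weight = "first", "ignore"))
    if (!weighted && !is.null(igraph::E(g)$weight)) {
      if (any(igraph::E(g)$weight != 1))
        warning("graph is unweighted: discarding edge weights")
      g <- igraph::delete_edge_attr(g, "weight")
    }
    if (weighted && is.null(igraph::E(g)$weight))
      igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  } else {
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (ncol(x) < 2L) stop("edge table needs at least two columns")
    src <- as.character(x[[1L]]); dst <- as.character(x[[2L]])
    w <- if (ncol(x) >= 3L) as.numeric(x[[3L]]) else rep(1, length(src))
    if (anyNA(w)) stop("non-numeric edge weight")
    if (!weighted && ncol(x) >= 3L && any(w != 1))
      warning("graph is unweighted: discarding edge weights")
    if (!weighted) w <- rep(1, length(src))
    labs <- vertices %||% unique(c(rbind(src, dst)))
    if (anyDuplicated(labs)) stop("duplicate vertex labels")
    miss <- setdiff(c(src, dst), labs)
    if (length(miss)) stop("edge endpoint(s) not in vertex set: ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    g <- igraph::make_empty_graph(n = length(labs), directed = directed)
    igraph::V(g)$name <- labs
    if (length(src))
      g <- igraph::add_edges(g, rbind(match(src, labs), match(dst, labs)))
    if (weighted) igraph::E(g)$weight <- w
  }
  if (weighted && igraph::ecount(g) && any(igraph::E(g)$weight <= 0))
    stop("edge weights must be strictly positive")
  if (simplify) g <- simplify_netgraph(g)
  validate_netgraph(g)
  g
}

#' Remove self-loops and duplicate edges
#'
#' Idempotent preprocessing applied before any measure: loops are dropped
#' and parallel edges collapsed, keeping the first weight seen.
#'
#' @param g an igraph object.
#' @return the simplified graph.
#' @export
simplify_netgraph <- function(g) {
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "first", "ignore"))
}

#' Validate the package's graph contract
#'
#' Checks labelled vertices, label uniqueness and strictly positive weights.
#' Called by constructors; exported for use on graphs built by hand.
#'
#' @param g an igraph object.
#' @return \code{g}, invisibly; errors describe the violated invariant.
#' @export
validate_netgraph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("every vertex must carry a non-empty label")
  if (anyDuplicated(nm)) stop("vertex labels must be unique")
  w <- igraph::E(g)$weight
  if (!is.null(w) && length(w) && (anyNA(w) || any(w <= 0)))
    stop("edge weights must be strictly positive")
  invisible(g)
}

#' @rdname as_netgraph
#' @export
is_weighted_graph <- function(x) "weight" %in% igraph::edge_attr_names(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

vertex_labels <- function(g) igraph::V(g)$name

# dense adjacency matrix; weights used when present unless use_weights=FALSE
adjacency_of <- function(g, use_weights = TRUE) {
  w <- if (use_weights && is_weighted_graph(g)) igraph::E(g)$weight else NULL
  as.matrix(igraph::as_adjacency_matrix(
    g, attr = if (is.null(w)) NULL else "weight", sparse = TRUE))
}

# geodesic distance matrix; weights read as distances (mode = "out" rows)
distances_of <- function(g, mode = "out") {
  igraph::distances(g, mode = mode)  # uses weight attribute when present
}
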