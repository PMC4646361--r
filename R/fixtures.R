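#' Deterministic test-network generators
#'
#' Reproducible graphs for examples, tests and demos: deterministic
#' families (path, cycle, star, complete), seeded random models
#' (Erdos-Renyi G(n, p), Barabasi-Albert preferential attachment) and the
#' packaged Zachary karate club network (34 vertices, 78 edges).
#'
#' @param kind one of \code{"path"}, \code{"cycle"}, \code{"star"},
#'   \code{"complete"}, \code{"erdos_renyi"}, \code{"barabasi_albert"},
#'   \code{"karate"}.
#' @param n number of vertices (ignored for \code{karate}).
#' @param p edge probability (\code{erdos_renyi}).
#' @param m edges added per step (\code{barabasi_albert}, default 1).
#' @param seed integer seed; mandatory for the random kinds.
#' @return \code{fixture_spec}: a validated spec object;
#'   \code{make_fixture}: the corresponding labelled igraph object
#'   (vertex labels \code{v1 ... vn}).
#' @examples
#' igraph::ecount(make_fixture(fixture_spec("star", n = 5)))
#' @export
fixture_spec <- function(kind = c("path", "cycle", "star", "complete",
                                  "erdos_renyi", "barabasi_albert",
                                  "karate"),
                         n = NULL, p = NULL, m = 1, seed = NULL) {
  kind <- match.arg(kind)
  if (kind != "karate") {
    if (is.null(n) || n < 1) stop("fixture '", kind, "' needs n >= 1")
    n <- as.integer(n)
  }
  if (kind == "erdos_renyi" && (is.null(p) || p < 0 || p > 1))
    stop("erdos_renyi needs p in [0, 1]")
  if (kind %in% c("erdos_renyi", "barabasi_albert") && is.null(seed))
    stop("random fixture '", kind, "' needs an explicit seed")
  structure(list(kind = kind, n = n, p = p, m = m, seed = seed),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @param spec a \code{fixture_spec} (or a kind string, forwarded with
#'   \code{...} to [fixture_spec()]).
#' @param ... forwarded to [fixture_spec()] when \code{spec} is a string.
#' @export
make_fixture <- function(spec, ...) {
  if (is.character(spec)) spec <- fixture_spec(spec, ...)
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n
  g <- switch(spec$kind,
    path = igraph::make_ring(n, circular = FALSE),
    cycle = igraph::make_ring(n, circular = TRUE),
    star = igraph::make_star(n, mode = "undirected", center = 1),
    complete = igraph::make_full_graph(n),
    erdos_renyi = with_seed(spec$seed,
      igraph::sample_gnp(n, spec$p, directed = FALSE)),
    barabasi_albert = with_seed(spec$seed,
      igraph::sample_pa(n, m = spec$m, directed = FALSE)),
    karate = igraph::read_graph(
      system.file("extdata", "karate.gml", package = "netcentral",
                  mustWork = TRUE), format = "gml"))
  if (spec$kind == "karate") {
    igraph::V(g)$name <- igraph::V(g)$label
  } else {
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  }
  for (a in igraph::graph_attr_names(g))   # drop generator metadata
    g <- igraph::delete_graph_attr(g, a)
  if ("label" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "label")
  g <- simplify_netgraph(g)
  validate_netgraph(g)
  g
}

#' Connected-graph atlas
#'
#' All connected graphs on up to \code{max_n} (at most 7) vertices, from
#' the canonical graph atlas ordering, as labelled igraph objects.  Used
#' by the oracle-equivalence test suites.
#'
#' @param max_n largest order to include (2..7; default 7).
#' @return list of igraph objects.
#' @export
graph_atlas_connected <- function(max_n = 7) {
  stopifnot(max_n >= 1, max_n <= 7)
  path <- system.file("extdata", "atlas_connected_le7.txt",
                      package = "netcentral", mustWork = TRUE)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!startsWith(ln, "#")]
  out <- list()
  for (l in ln) {
    bits <- strsplit(l, ";", fixed = TRUE)[[1L]]
    n <- as.integer(bits[1L])
    if (n > max_n) next
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (length(bits) > 1L && nzchar(bits[2L])) {
      pr <- do.call(rbind, strsplit(strsplit(bits[2L], ",")[[1L]], "-"))
      g <- igraph::add_edges(g, t(matrix(as.integer(pr), ncol = 2L) + 1L))
    }
    igraph::V(g)$name <- paste0("v", seq_len(n))
    out[[length(out) + 1L]] <- g
  }
  out
}

# resolve "fixture:<kind>[:n[:seed]]" pseudo-paths used by the job runner
resolve_fixture_path <- function(path) {
  if (!startsWith(path, "fixture:")) return(NULL)
  bits <- strsplit(path, ":", fixed = TRUE)[[1L]][-1L]
  kind <- bits[1L]
  n <- if (length(bits) >= 2L) as.integer(bits[2L]) else NULL
  seed <- if (length(bits) >= 3L) as.integer(bits[3L]) else NULL
  if (kind == "erdos_renyi")
    make_fixture(fixture_spec(kind, n = n, p = 0.2, seed = seed))
  else if (kind == "barabasi_albert")
    make_fixture(fixture_spec(kind, n = n, seed = seed))
  else make_fixture(fixture_spec(kind, n = n))
}
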