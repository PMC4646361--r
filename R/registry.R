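#' Per-measure score vector
#'
#' The common result container: one finite real score per vertex, plus the
#' measure id and the parameter values used.
#'
#' @param measure_id registry id of the measure.
#' @param scores named numeric vector, names = vertex labels.
#' @param params named list of parameter values actually used.
#' @param extra optional named list of secondary outputs (e.g. HITS hub
#'   scores, graphlet orbit matrices).
#' @return an object of class \code{score_vector}.
#' @export
score_vector <- function(measure_id, scores, params = list(), extra = NULL) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("non-finite score produced by '", measure_id, "'")
  structure(list(measure_id = measure_id, params = params,
                 scores = scores, extra = extra),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat("<score_vector>", x$measure_id, "over", length(x$scores), "vertices\n")
  print(utils::head(sort(x$scores, decreasing = TRUE), 5L))
  invisible(x)
}

#' @export
as.data.frame.score_vector <- function(x, ...) {
  data.frame(node = names(x$scores), measure = x$measure_id,
             score = unname(x$scores), stringsAsFactors = FALSE)
}

mk_param <- function(name, default, min = -Inf, max = Inf, kind = "numeric")
  list(name = name, default = default, min = min, max = max, kind = kind)

registry_rows <- function() {
  r <- list()
  add <- function(id, name, family, dir, wt, params = list())
    r[[length(r) + 1L]] <<- list(id = id, name = name, family = family,
                                 supports_directed = dir,
                                 supports_weighted = wt, params = params)
  ## distance family -----------------------------------------------------
  add("closeness_freeman",   "Closeness centrality (Freeman)",   "distance", TRUE, TRUE)
  add("closeness_latora",    "Closeness centrality (Latora)",    "distance", TRUE, TRUE)
  add("closeness_dangalchev","Dangalchev closeness centrality",  "distance", TRUE, TRUE)
  add("barycenter",          "Barycenter centrality",            "distance", TRUE, TRUE)
  add("lin",                 "Lin centrality",                   "distance", TRUE, TRUE)
  add("eccentricity",        "Eccentricity centrality",          "distance", TRUE, TRUE)
  add("radiality",           "Radiality centrality",             "distance", TRUE, TRUE)
  add("centroid_value",      "Centroid value",                   "distance", TRUE, TRUE)
  add("decay",               "Decay centrality",                 "distance", TRUE, TRUE,
      list(mk_param("delta", 0.5, 0, 1)))
  add("average_distance",    "Average distance",                 "distance", TRUE, TRUE)
  add("closeness_vitality",  "Closeness vitality",               "distance", TRUE, TRUE)
  add("geodesic_kpath",      "Geodesic K-path centrality",       "distance", TRUE, TRUE,
      list(mk_param("k", 3, 1, Inf, "integer")))
  ## neighborhood family -------------------------------------------------
  add("degree",   "Degree centrality",                "neighborhood", TRUE,  FALSE,
      list(mk_param("mode", "total", kind = "choice:total,in,out")))
  add("strength", "Strength (weighted vertex degree)","neighborhood", TRUE,  TRUE,
      list(mk_param("mode", "total", kind = "choice:total,in,out")))
  add("lobby",    "Lobby index",                      "neighborhood", FALSE, FALSE)
  add("leverage", "Leverage centrality",              "neighborhood", FALSE, FALSE)
  add("local_clustering", "Local clustering coefficients", "neighborhood", FALSE, FALSE)
  add("topological_coefficient", "Topological coefficient", "neighborhood", FALSE, FALSE)
  add("kcore",    "K-core decomposition",             "neighborhood", FALSE, FALSE)
  add("semilocal","Semi local centrality",            "neighborhood", FALSE, FALSE)
  add("clusterrank", "ClusterRank",                   "neighborhood", TRUE,  FALSE)
  add("diffusion_degree", "Diffusion degree",         "neighborhood", FALSE, FALSE,
      list(mk_param("lambda", 1.0, 0, Inf)))
  add("mnc",  "MNC (Maximum Neighborhood Component)", "neighborhood", FALSE, FALSE)
  add("dmnc", "DMNC (Density of Maximum Neighborhood Component)",
      "neighborhood", FALSE, FALSE, list(mk_param("epsilon", 1.7, 1, 2)))
  add("cross_clique", "Cross clique connectivity",    "neighborhood", FALSE, FALSE)
  add("burt_constraint", "Burt's constraint",         "neighborhood", FALSE, TRUE)
  add("graphlet_degree", "Graphlet degree centrality","neighborhood", FALSE, FALSE,
      list(mk_param("max_size", 4, 3, 4, "integer")))
  ## feedback family -----------------------------------------------------
  add("eigenvector", "Eigenvector centrality", "feedback", TRUE, TRUE)
  add("katz", "Katz status index", "feedback", TRUE, TRUE,
      list(mk_param("alpha", NA_real_, 0, Inf)))   # NA -> 0.5 / lambda_max
  add("alpha_centrality", "Alpha centrality", "feedback", TRUE, TRUE,
      list(mk_param("alpha", NA_real_, 0, Inf), mk_param("exo", 1)))
  add("bonacich_power", "Bargaining centrality (Bonacich power)", "feedback",
      TRUE, TRUE, list(mk_param("alpha", 1), mk_param("beta", NA_real_)))
  add("hubbell", "Hubbell index", "feedback", TRUE, TRUE,
      list(mk_param("weight_factor", NA_real_), mk_param("exo", 1)))
  add("pagerank", "PageRank", "feedback", TRUE, TRUE,
      list(mk_param("damping", 0.85, 0, 1), mk_param("tol", 1e-8, 0, Inf),
           mk_param("max_iter", 1e5, 1, Inf, "integer")))
  add("leaderrank", "LeaderRank", "feedback", TRUE, FALSE,
      list(mk_param("tol", 1e-8, 0, Inf),
           mk_param("max_iter", 1e5, 1, Inf, "integer")))
  add("hits", "Kleinberg's (HITS)", "feedback", TRUE, TRUE,
      list(mk_param("tol", 1e-8, 0, Inf),
           mk_param("max_iter", 1e5, 1, Inf, "integer")))
  add("salsa", "SALSA (Stochastic Approach for Link-Structure Analysis)",
      "feedback", TRUE, FALSE,
      list(mk_param("tol", 1e-10, 0, Inf),
           mk_param("max_iter", 1e5, 1, Inf, "integer")))
  add("subgraph", "Subgraph centrality", "feedback", FALSE, TRUE)
  add("laplacian", "Laplacian centrality", "feedback", FALSE, TRUE)
  add("entropy", "Entropy centrality", "feedback", FALSE, FALSE,
      list(mk_param("samples", 2000, 1, Inf, "integer"),
           mk_param("exact_limit", 12, 0, Inf, "integer"),
           mk_param("seed", 1, kind = "integer")))
  add("community", "Community centrality", "feedback", FALSE, FALSE)
  ## flow family ---------------------------------------------------------
  flowp <- list(mk_param("normalized", FALSE, kind = "logical"))
  add("betweenness", "Shortest-paths betweenness centrality", "flow",
      TRUE, TRUE, flowp)
  add("stress", "Stress centrality", "flow", TRUE, TRUE, flowp)
  add("load", "Load centrality", "flow", TRUE, TRUE, flowp)
  add("flow_betweenness", "Flow betweenness centrality", "flow", TRUE, TRUE, flowp)
  add("current_flow_betweenness", "Current flow betweenness centrality",
      "flow", FALSE, TRUE, flowp)
  add("current_flow_closeness", "Current flow closeness centrality",
      "flow", FALSE, TRUE)
  add("information", "Information centrality", "flow", FALSE, TRUE)
  add("communicability_betweenness", "Communicability betweenness centrality",
      "flow", FALSE, TRUE)
  add("markov", "Markov centrality", "flow", TRUE, TRUE)
  ## perturbation family -------------------------------------------------
  add("bottleneck", "Bottleneck", "perturbation", TRUE, FALSE)
  add("bridging", "Bridging centrality", "perturbation", FALSE, FALSE)
  add("epc", "EPC (Edge Percolated Component)", "perturbation", FALSE, FALSE,
      list(mk_param("retention", 0.5, 0, 1),
           mk_param("samples", 1000, 1, Inf, "integer"),
           mk_param("seed", 1, kind = "integer")))
  add("pairwise_disconnectivity", "Pairwise disconnectivity index",
      "perturbation", TRUE, FALSE)
  r
}

.registry_env <- new.env(parent = emptyenv())

measure_registry_list <- function() {
  if (is.null(.registry_env$rows)) .registry_env$rows <- registry_rows()
  .registry_env$rows
}

#' List the available centrality measures
#'
#' Returns the measure registry as a data frame, listed alphabetically by
#' display name: id, name, family, directed/weighted applicability and the
#' parameter signature with defaults.
#'
#' @param family optional filter: one of \code{"distance"},
#'   \code{"neighborhood"}, \code{"feedback"}, \code{"flow"},
#'   \code{"perturbation"}.
#' @return a data frame with one row per measure.
#' @examples
#' nrow(list_measures())          # 53 measures
#' list_measures("perturbation")$id
#' @export
list_measures <- function(family = NULL) {
  rows <- measure_registry_list()
  df <- do.call(rbind, lapply(rows, function(m) data.frame(
    id = m$id, name = m$name, family = m$family,
    supports_directed = m$supports_directed,
    supports_weighted = m$supports_weighted,
    params = paste(vapply(m$params, function(p)
      paste0(p$name, "=", format(p$default)), ""), collapse = ", "),
    stringsAsFactors = FALSE)))
  if (!is.null(family)) {
    fam <- match.arg(family, c("distance", "neighborhood", "feedback",
                               "flow", "perturbation"))
    df <- df[df$family == fam, , drop = FALSE]
  }
  df <- df[order(df$name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

measure_descriptor <- function(measure_id) {
  rows <- measure_registry_list()
  ids <- vapply(rows, `[[`, "", "id")
  i <- match(measure_id, ids)
  if (is.na(i)) stop("unknown measure id '", measure_id,
                     "' (see list_measures())")
  rows[[i]]
}

resolve_params <- function(desc, params) {
  out <- list()
  known <- vapply(desc$params, `[[`, "", "name")
  bad <- setdiff(names(params), known)
  if (length(bad)) stop("unknown parameter(s) for '", desc$id, "': ",
                        paste(bad, collapse = ", "))
  for (p in desc$params) {
    v <- if (p$name %in% names(params)) params[[p$name]] else p$default
    if (is.numeric(v) && !is.na(p$min) && is.finite(p$min) && !is.na(v)) {
      if (v < p$min || v > p$max)
        stop("parameter '", p$name, "' of '", desc$id, "' out of range [",
             p$min, ", ", p$max, "]")
    }
    if (startsWith(p$kind %||% "numeric", "choice:")) {
      choices <- strsplit(sub("^choice:", "", p$kind), ",")[[1L]]
      v <- match.arg(v, choices)
    }
    out[[p$name]] <- v
  }
  out
}

#' Compute one centrality measure
#'
#' The single dispatch point over the whole measure registry.  Validates
#' the measure id and parameters, reconciles the graph with the measure's
#' directed/weighted applicability (unsupported directionality is reduced
#' to the underlying undirected graph, unsupported weights are dropped;
#' both with a warning), and calls the family implementation.
#'
#' @param g a labelled igraph object (see [as_netgraph()]).
#' @param measure_id a registry id, e.g. \code{"betweenness"};
#'   see [list_measures()].
#' @param params named list of measure parameters overriding the registry
#'   defaults.
#' @return a [score_vector].
#' @examples
#' g <- make_fixture(fixture_spec("star", n = 5))
#' centrality_score(g, "degree")$scores
#' @export
centrality_score <- function(g, measure_id, params = list()) {
  validate_netgraph(g)
  desc <- measure_descriptor(measure_id)
  pars <- resolve_params(desc, params)
  if (igraph::is_directed(g) && !desc$supports_directed) {
    warning("'", measure_id, "' is defined for undirected graphs; ",
            "using the underlying undirected graph")
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "first", "ignore"))
  }
  if (is_weighted_graph(g) && !desc$supports_weighted) {
    if (any(igraph::E(g)$weight != 1))
      warning("'", measure_id, "' ignores edge weights")
    g <- igraph::delete_edge_attr(g, "weight")
  }
  fam_fun <- switch(desc$family,
    distance = distance_score, neighborhood = neighborhood_score,
    feedback = feedback_score, flow = flow_score,
    perturbation = perturbation_score)
  sv <- fam_fun(g, measure_id, pars)
  labs <- vertex_labels(g)
  stopifnot(setequal(names(sv$scores), labs))
  sv$scores <- sv$scores[labs]
  sv
}
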