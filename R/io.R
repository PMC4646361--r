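#' Read a network file
#'
#' Parses one of the five supported network formats into the package's
#' graph representation.  Formats:
#' \describe{
#'   \item{edgelist}{whitespace-separated source / target / optional weight
#'     columns; lines starting with \code{#} are ignored.}
#'   \item{pajek}{\code{*Vertices} / \code{*Edges} / \code{*Arcs} sections.}
#'   \item{ucinet_dl}{UCINET DL, \code{format = fullmatrix} or
#'     \code{edgelist1} dialects.}
#'   \item{gml}{Graph Modelling Language.}
#'   \item{graphml}{GraphML XML.}
#' }
#' Vertex labels are case-sensitive strings; numeric ids in Pajek / DL
#' files become their declared label when one is given, else their ordinal
#' as a string.  Vertex order is first-appearance order.
#'
#' @param path file path.
#' @param format one of \code{"edgelist"}, \code{"pajek"},
#'   \code{"ucinet_dl"}, \code{"gml"}, \code{"graphml"}; \code{"auto"}
#'   guesses from the file extension (.txt .net .dl .gml .graphml).
#' @param directed,weighted,simplify see [as_netgraph()].
#' @return an igraph object with labelled vertices.
#' @examples
#' p <- tempfile(fileext = ".txt")
#' writeLines(c("a b", "b c 2.5"), p)
#' g <- read_graph_file(p, "edgelist", weighted = TRUE)
#' igraph::ecount(g)
#' @export
read_graph_file <- function(path,
                            format = c("auto", "edgelist", "pajek",
                                       "ucinet_dl", "gml", "graphml"),
                            directed = FALSE, weighted = FALSE,
                            simplify = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
      txt = "edgelist", net = "pajek", dl = "ucinet_dl",
      gml = "gml", graphml = "graphml",
      stop("cannot guess format from extension '.", ext, "'"))
  }
  el <- switch(format,
    edgelist  = parse_edgelist(path),
    pajek     = parse_pajek(path),
    ucinet_dl = parse_ucinet_dl(path),
    gml       = igraph_edge_table(path, "gml"),
    graphml   = igraph_edge_table(path, "graphml"))
  as_netgraph(el$edges, directed = directed, weighted = weighted,
              simplify = simplify, vertices = el$vertices)
}

parse_edgelist <- function(path) {
  ln <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", ln))
  src <- character(0); dst <- character(0); w <- numeric(0)
  for (i in keep) {
    tok <- strsplit(trimws(ln[i]), "\\s+")[[1L]]
    if (length(tok) < 2L)
      stop("edge list parse error at line ", i, ": need >= 2 columns")
    wt <- if (length(tok) >= 3L) suppressWarnings(as.numeric(tok[3L])) else 1
    if (is.na(wt))
      stop("edge list parse error at line ", i, ": bad weight '", tok[3L], "'")
    src <- c(src, tok[1L]); dst <- c(dst, tok[2L]); w <- c(w, wt)
  }
  list(edges = data.frame(src, dst, w, stringsAsFactors = FALSE),
       vertices = NULL)
}

parse_pajek <- function(path) {
  ln <- readLines(path, warn = FALSE)
  sec <- ""; labs <- character(0)
  src <- character(0); dst <- character(0); w <- numeric(0)
  lab_of <- function(i) if (i <= length(labs) && !is.na(labs[i]) &&
                            nzchar(labs[i])) labs[i] else as.character(i)
  for (i in seq_along(ln)) {
    l <- trimws(ln[i])
    if (!nzchar(l) || startsWith(l, "%")) next
    if (startsWith(tolower(l), "*")) {
      key <- tolower(strsplit(l, "\\s+")[[1L]][1L])
      if (startsWith(key, "*vertices")) {
        sec <- "v"
        n <- suppressWarnings(as.integer(strsplit(l, "\\s+")[[1L]][2L]))
        if (is.na(n)) stop("Pajek parse error at line ", i,
                           ": *Vertices needs a count")
        labs <- rep(NA_character_, n)
      } else if (key %in% c("*edges", "*arcs")) sec <- "e"
      else stop("Pajek parse error at line ", i,
                ": unsupported section ", key)
      next
    }
    if (sec == "v") {
      m <- regmatches(l, regexec('^(\\d+)\\s+"([^"]*)"', l))[[1L]]
      if (!length(m)) m <- regmatches(l, regexec("^(\\d+)\\s+(\\S+)", l))[[1L]]
      if (!length(m)) stop("Pajek parse error at line ", i)
      labs[as.integer(m[2L])] <- m[3L]
    } else if (sec == "e") {
      tok <- strsplit(l, "\\s+")[[1L]]
      if (length(tok) < 2L) stop("Pajek parse error at line ", i)
      a <- suppressWarnings(as.integer(tok[1L]))
      b <- suppressWarnings(as.integer(tok[2L]))
      if (is.na(a) || is.na(b)) stop("Pajek parse error at line ", i)
      wt <- if (length(tok) >= 3L) suppressWarnings(as.numeric(tok[3L])) else 1
      if (is.na(wt)) stop("Pajek parse error at line ", i, ": bad weight")
      src <- c(src, lab_of(a)); dst <- c(dst, lab_of(b)); w <- c(w, wt)
    } else stop("Pajek parse error at line ", i, ": data before section")
  }
  verts <- if (length(labs)) vapply(seq_along(labs), lab_of, "") else NULL
  list(edges = data.frame(src, dst, w, stringsAsFactors = FALSE),
       vertices = verts)
}

parse_ucinet_dl <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (!length(ln) || !grepl("^dl\\b", tolower(trimws(ln[1L]))))
    stop("UCINET DL parse error: file must start with 'dl'")
  header <- trimws(ln[1L])
  n <- as.integer(sub(".*n\\s*=\\s*(\\d+).*", "\\1", tolower(header)))
  if (is.na(n)) stop("UCINET DL parse error: header lacks n=")
  fmt <- "fullmatrix"
  i <- 2L
  labs <- NULL
  body <- NULL
  while (i <= length(ln)) {
    l <- trimws(ln[i]); ll <- tolower(l)
    if (grepl("^format\\s*=", ll)) {
      fmt <- sub("^format\\s*=\\s*", "", ll)
    } else if (grepl("^labels\\s*:?", ll)) {
      labs <- character(0)
      if (grepl(":", l) && nzchar(sub("^[^:]*:", "", l)))
        labs <- strsplit(trimws(sub("^[^:]*:", "", l)), "[,\\s]+")[[1L]]
      while (length(labs) < n && i < length(ln) &&
             !grepl("^(data|format|labels)", tolower(trimws(ln[i + 1L])))) {
        i <- i + 1L
        labs <- c(labs, strsplit(trimws(ln[i]), "[,\\s]+")[[1L]])
      }
      labs <- gsub('^"|"$', "", labs)
    } else if (grepl("^data\\s*:?$", ll)) {
      body <- ln[seq.int(i + 1L, length(ln))]
      break
    }
    i <- i + 1L
  }
  if (is.null(body)) stop("UCINET DL parse error: no data: section")
  lab_of <- function(k) if (!is.null(labs) && k <= length(labs))
    labs[k] else as.character(k)
  verts <- vapply(seq_len(n), lab_of, "")
  src <- character(0); dst <- character(0); w <- numeric(0)
  if (grepl("fullmatrix", fmt)) {
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
    if (anyNA(vals) || length(vals) != n * n)
      stop("UCINET DL parse error: fullmatrix needs ", n * n,
           " numeric entries, got ", length(vals))
    m <- matrix(vals, nrow = n, byrow = TRUE)
    idx <- which(m != 0, arr.ind = TRUE)
    if (nrow(idx)) {
      src <- verts[idx[, 1L]]; dst <- verts[idx[, 2L]]
      w <- m[idx]
    }
  } else if (grepl("edgelist1", fmt)) {
    for (l in trimws(body)) {
      tok <- strsplit(l, "\\s+")[[1L]]
      if (length(tok) < 2L) stop("UCINET DL parse error: bad edge row '", l, "'")
      ab <- suppressWarnings(as.integer(tok[1:2]))
      if (anyNA(ab)) { # labelled edge rows
        src <- c(src, tok[1L]); dst <- c(dst, tok[2L])
      } else {
        src <- c(src, lab_of(ab[1L])); dst <- c(dst, lab_of(ab[2L]))
      }
      wt <- if (length(tok) >= 3L) suppressWarnings(as.numeric(tok[3L])) else 1
      if (is.na(wt)) stop("UCINET DL parse error: bad weight in '", l, "'")
      w <- c(w, wt)
    }
  } else stop("UCINET DL parse error: unsupported format '", fmt,
              "' (fullmatrix and edgelist1 only)")
  list(edges = data.frame(src, dst, w, stringsAsFactors = FALSE),
       vertices = verts)
}

# GML / GraphML via igraph's readers, normalised to an edge table so that
# label recovery and weight handling are uniform across formats
igraph_edge_table <- function(path, fmt) {
  g <- tryCatch(igraph::read_graph(path, format = fmt),
                error = function(e) stop(toupper(fmt), " parse error in '",
                                         path, "': ", conditionMessage(e)))
  labs <- igraph::V(g)$name %||% igraph::V(g)$label %||%
    as.character(igraph::V(g)$id %||% seq_len(igraph::vcount(g)))
  labs <- as.character(labs)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight %||% rep(1, nrow(el))
  list(edges = data.frame(src = labs[el[, 1L]], dst = labs[el[, 2L]],
                          w = w, stringsAsFactors = FALSE),
       vertices = labs)
}

#' Write a network file
#'
#' Writes GML or GraphML through \pkg{igraph} (vertex labels stored in the
#' \code{name}/\code{label} attribute, weights in \code{weight}); the other
#' read formats are write-supported for round-trip convenience.
#'
#' @param g graph; @param path output path;
#' @param format \code{"gml"}, \code{"graphml"}, \code{"edgelist"} or
#'   \code{"pajek"}.
#' @return \code{path}, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("gml", "graphml",
                                                 "edgelist", "pajek")) {
  format <- match.arg(format)
  validate_netgraph(g)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g)
    w <- if (is_weighted_graph(g)) paste0(" ", format_score(igraph::E(g)$weight)) else ""
    writeLines(paste0(el[, 1L], " ", el[, 2L], w), path)
  } else if (format == "pajek") {
    con <- file(path, "w"); on.exit(close(con))
    labs <- vertex_labels(g)
    writeLines(sprintf("*Vertices %d", length(labs)), con)
    writeLines(sprintf('%d "%s"', seq_along(labs), labs), con)
    writeLines(if (igraph::is_directed(g)) "*Arcs" else "*Edges", con)
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- if (is_weighted_graph(g)) igraph::E(g)$weight else rep(1, nrow(el))
    writeLines(paste(el[, 1L], el[, 2L], format_score(w)), con)
  } else if (format == "gml") {
    write_gml_impl(g, path)
  } else {
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

# deterministic GML emitter (igraph's writer stamps a Creator line with
# the current time and strips '_' from attribute keys)
write_gml_impl <- function(g, path, node_attrs = list()) {
  labs <- vertex_labels(g)
  con <- file(path, "w"); on.exit(close(con))
  esc <- function(x) gsub('"', "'", x)
  writeLines(c("Creator \"netcentral\"", "graph", "[",
               paste0("  directed ", as.integer(igraph::is_directed(g)))),
             con)
  for (i in seq_along(labs)) {
    block <- c("  node", "  [", paste0("    id ", i - 1L),
               paste0('    label "', esc(labs[i]), '"'))
    for (key in names(node_attrs))
      block <- c(block, paste0("    ", key, " ",
                               format_score(node_attrs[[key]][i])))
    writeLines(c(block, "  ]"), con)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (is_weighted_graph(g)) igraph::E(g)$weight else NULL
  for (k in seq_len(nrow(el))) {
    block <- c("  edge", "  [",
               paste0("    source ", el[k, 1L] - 1L),
               paste0("    target ", el[k, 2L] - 1L))
    if (!is.null(w))
      block <- c(block, paste0("    weight ", format_score(w[k])))
    writeLines(c(block, "  ]"), con)
  }
  writeLines("]", con)
  invisible(path)
}

#' Export centrality scores as CSV
#'
#' One row per vertex (graph vertex order), one column per measure;
#' header row is \code{node} followed by the measure ids.  RFC 4180
#' quoting; scores printed with 12 significant digits.
#'
#' @param results a single [score_vector] or a list of them, all computed
#'   on the same vertex set; may be an empty list when \code{g} is given.
#' @param path output path.
#' @param g graph supplying the vertex order (and the vertex list when
#'   \code{results} is empty); defaults to the score vectors' own order.
#' @return \code{path}, invisibly.
#' @export
write_scores_csv <- function(results, path, g = NULL) {
  results <- as_score_list(results, allow_empty = !is.null(g))
  labs <- if (length(results)) score_universe(results) else character(0)
  if (!is.null(g)) {
    if (length(results) && !setequal(labs, vertex_labels(g)))
      stop("score vertex set does not match the graph")
    labs <- vertex_labels(g)
  }
  df <- data.frame(node = labs, stringsAsFactors = FALSE)
  for (sv in results) df[[sv$measure_id]] <- format_score(sv$scores[labs])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Export a score-annotated GML file
#'
#' Writes the graph in GML with one numeric vertex attribute per measure;
#' attribute keys are the measure ids sanitised to \code{[A-Za-z0-9_]}.
#'
#' @inheritParams write_scores_csv
#' @param g the graph the scores were computed on.
#' @return \code{path}, invisibly.
#' @export
write_gml_annotated <- function(g, results, path) {
  validate_netgraph(g)
  results <- as_score_list(results)
  labs <- score_universe(results)
  if (!setequal(labs, vertex_labels(g)))
    stop("score vertex set does not match the graph")
  attrs <- list()
  for (sv in results)
    attrs[[sanitize_key(sv$measure_id)]] <-
      unname(sv$scores[vertex_labels(g)])
  write_gml_impl(g, path, node_attrs = attrs)
  invisible(path)
}

sanitize_key <- function(id) {
  key <- gsub("[^A-Za-z0-9_]+", "_", gsub("'", "", tolower(id)))
  gsub("^_+|_+$", "", key)
}

format_score <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  trimws(out)
}

as_score_list <- function(results, allow_empty = FALSE) {
  if (inherits(results, "score_vector")) results <- list(results)
  if (!length(results) && !allow_empty) stop("no score vectors given")
  lapply(results, function(sv) {
    if (!inherits(sv, "score_vector")) stop("expected score_vector objects")
    sv
  })
}

score_universe <- function(results) {
  labs <- names(results[[1L]]$scores)
  for (sv in results)
    if (!identical(sort(names(sv$scores)), sort(labs)))
      stop("score vectors cover different vertex sets")
  labs
}
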