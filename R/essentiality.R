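#' Rank vertices by a centrality score
#'
#' Stable total order over the vertex labels, best score first, ties
#' broken by lexicographic label order (C locale), optionally truncated
#' to the top \code{top_m}.
#'
#' @param scores a [score_vector] or a named numeric vector.
#' @param descending logical; rank high scores first (default).
#' @param top_m optional truncation length.
#' @return an object of class \code{ranked_list}: \code{measure_id},
#'   \code{labels} (best first), \code{tie_break}, \code{universe_size}.
#' @examples
#' rank_vertices(c(a = 3, b = 1, c = 2))$labels
#' @export
rank_vertices <- function(scores, descending = TRUE, top_m = NULL) {
  measure_id <- "scores"
  if (inherits(scores, "score_vector")) {
    measure_id <- scores$measure_id
    scores <- scores$scores
  }
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores must be finite to be ranked")
  n <- length(scores)
  if (!is.null(top_m) && (top_m < 1 || top_m > n))
    stop("top_m must be between 1 and ", n)
  key <- if (descending) -scores else scores
  ord <- order(key, names(scores), method = "radix")
  labels <- names(scores)[ord]
  if (!is.null(top_m)) labels <- labels[seq_len(top_m)]
  structure(list(measure_id = measure_id, labels = labels,
                 tie_break = "lexicographic", universe_size = n),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("<ranked_list>", x$measure_id, "top of", x$universe_size,
      "vertices:", paste(utils::head(x$labels, 10L), collapse = " > "), "\n")
  invisible(x)
}

#' Essential-node enrichment in the top k
#'
#' Percentage of a reference "essential" label set found among the k
#' best-ranked vertices: \eqn{100 |top_k \cap essential| / k}.  This is
#' the centrality-lethality readout used to compare measures on
#' protein-protein interaction networks.
#'
#' @param ranked a [rank_vertices()] result (or plain character vector,
#'   best first).
#' @param essential character vector of essential labels.
#' @param k depth of the prefix to inspect.
#' @return a percentage in [0, 100].
#' @examples
#' r <- rank_vertices(c(a = 4, b = 3, c = 2, d = 1))
#' topk_enrichment(r, c("a", "c"), k = 2)
#' @export
topk_enrichment <- function(ranked, essential, k) {
  labels <- if (inherits(ranked, "ranked_list")) ranked$labels else
    as.character(ranked)
  if (k < 1 || k > length(labels))
    stop("k must be between 1 and ", length(labels))
  if (!length(essential)) {
    warning("empty essential set: enrichment is 0")
    return(0)
  }
  100 * sum(labels[seq_len(k)] %in% essential) / k
}

#' Read an essential-node set
#'
#' One label per line; blank lines and \code{#} comments ignored.
#'
#' @param path file path.
#' @return character vector of labels.
#' @export
read_essential_set <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  unique(ln[nzchar(ln) & !startsWith(ln, "#")])
}

#' Aggregate ranked lists into a consensus ranking
#'
#' Finds a consensus permutation of the label universe minimising the
#' total (weighted) distance to the input orderings, the way per-measure
#' protein rankings are merged into one essentiality ranking.  The
#' Spearman distance is the footrule \eqn{\sum_i |r_1(i) - r_2(i)|};
#' Kendall counts discordant pairs.  Truncated lists are extended by
#' assigning every absent item the tied rank \eqn{m + 1}.
#'
#' Search is exhaustive over all permutations when the universe has at
#' most 8 labels (or when \code{method = "exhaustive"}), otherwise a
#' seeded genetic algorithm: permutation-encoded population seeded with
#' the input lists, order crossover, swap mutation, elitist selection,
#' stopping after \code{convergence_window} generations without
#' improvement.
#'
#' @param lists list of [rank_vertices()] results (or character vectors).
#' @param distance \code{"spearman"} (footrule, default) or
#'   \code{"kendall"}.
#' @param method \code{"auto"} (default), \code{"genetic"} or
#'   \code{"exhaustive"}.
#' @param weights optional per-list importance weights (default 1).
#' @param population,max_iter,convergence_window,cx_prob,mut_prob genetic
#'   algorithm controls (defaults 100, 1000, 15, 0.4, 0.01).
#' @param seed integer seed for the genetic search; required for
#'   reproducibility.
#' @return an object of class \code{rank_aggregation}: \code{consensus}
#'   (ordered labels), \code{objective}, \code{method}, \code{distance},
#'   \code{seed}, \code{iterations}.
#' @examples
#' out <- aggregate_ranks(list(c("a", "b", "c"), c("a", "c", "b"),
#'                             c("a", "b", "c")), seed = 1)
#' out$consensus
#' @export
aggregate_ranks <- function(lists,
                            distance = c("spearman", "kendall"),
                            method = c("auto", "genetic", "exhaustive"),
                            weights = NULL, population = 100,
                            max_iter = 1000, convergence_window = 15,
                            cx_prob = 0.4, mut_prob = 0.01, seed = 1) {
  distance <- match.arg(distance)
  method <- match.arg(method)
  if (length(lists) < 2L) stop("need at least two ranked lists")
  labs_of <- function(l) if (inherits(l, "ranked_list")) l$labels else
    as.character(l)
  lls <- lapply(lists, labs_of)
  for (l in lls) if (anyDuplicated(l))
    stop("a ranked list contains duplicate labels")
  universe <- sort(unique(unlist(lls)), method = "radix")
  N <- length(universe)
  weights <- if (is.null(weights)) rep(1, length(lls)) else
    rep_len(weights, length(lls))
  # rank of each universe item in each input list; absent items get the
  # tied extension rank m + 1
  R <- vapply(lls, function(l) {
    r <- match(universe, l)
    r[is.na(r)] <- length(l) + 1L
    r
  }, numeric(N))

  objective_of <- function(perm_idx) {
    cr <- integer(N); cr[perm_idx] <- seq_len(N)   # consensus ranks
    if (distance == "spearman") {
      sum(weights * colSums(abs(R - cr)))
    } else {
      sum(weights * apply(R, 2L, function(r) kendall_dist(cr, r)))
    }
  }

  if (method == "auto") method <- if (N <= 8L) "exhaustive" else "genetic"
  iterations <- 0L
  if (method == "exhaustive") {
    if (N > 9L) stop("exhaustive search refused for more than 9 labels")
    best <- NULL; best_obj <- Inf
    perms <- all_permutations(N)
    iterations <- nrow(perms)
    for (i in seq_len(nrow(perms))) {
      o <- objective_of(perms[i, ])
      if (o < best_obj) { best_obj <- o; best <- perms[i, ] }
    }
  } else {
    ga <- with_seed(seed, ga_search(R, weights, distance, objective_of, N,
                                    population, max_iter,
                                    convergence_window, cx_prob, mut_prob))
    best <- ga$best; best_obj <- ga$objective; iterations <- ga$iterations
  }
  structure(list(consensus = universe[best], objective = best_obj,
                 method = method, distance = distance, seed = seed,
                 iterations = iterations),
            class = "rank_aggregation")
}

#' @export
print.rank_aggregation <- function(x, ...) {
  cat("<rank_aggregation>", x$method, "/", x$distance, "objective",
      format(x$objective), "\n  consensus:",
      paste(utils::head(x$consensus, 10L), collapse = " > "),
      if (length(x$consensus) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Recompute the objective of a consensus ordering
#'
#' @param consensus character vector (ordered labels covering the
#'   universe).
#' @param lists,distance,weights as in [aggregate_ranks()].
#' @return the summed weighted distance.
#' @export
aggregation_objective <- function(consensus, lists,
                                  distance = c("spearman", "kendall"),
                                  weights = NULL) {
  distance <- match.arg(distance)
  lls <- lapply(lists, function(l)
    if (inherits(l, "ranked_list")) l$labels else as.character(l))
  weights <- if (is.null(weights)) rep(1, length(lls)) else
    rep_len(weights, length(lls))
  cr <- stats::setNames(seq_along(consensus), consensus)
  tot <- 0
  for (i in seq_along(lls)) {
    r <- match(names(cr), lls[[i]])
    r[is.na(r)] <- length(lls[[i]]) + 1L
    tot <- tot + weights[i] *
      (if (distance == "spearman") sum(abs(r - cr)) else
         kendall_dist(unname(cr), r))
  }
  tot
}

kendall_dist <- function(r1, r2) {
  n <- length(r1); d <- 0
  for (i in seq_len(n - 1L)) {
    a <- sign(r1[i] - r1[(i + 1L):n]); b <- sign(r2[i] - r2[(i + 1L):n])
    d <- d + sum(a * b < 0)
  }
  d
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

ga_search <- function(R, weights, distance, objective_of, N, population,
                      max_iter, convergence_window, cx_prob, mut_prob) {
  # seed the population with the input orderings themselves
  pop <- vector("list", population)
  nseed <- min(ncol(R), population %/% 2L)
  for (i in seq_len(nseed)) pop[[i]] <- order(R[, i], seq_len(N))
  for (i in seq.int(nseed + 1L, population)) pop[[i]] <- sample.int(N)
  fit <- vapply(pop, objective_of, 0)
  best_i <- which.min(fit)
  best <- pop[[best_i]]; best_obj <- fit[best_i]
  stale <- 0L; it <- 0L
  while (it < max_iter && stale < convergence_window) {
    it <- it + 1L
    # tournament selection
    newpop <- vector("list", population)
    newpop[[1L]] <- best                      # elitism
    for (i in seq.int(2L, population)) {
      cand <- sample.int(population, 2L)
      parent <- pop[[cand[which.min(fit[cand])]]]
      if (stats::runif(1) < cx_prob) {
        cand2 <- sample.int(population, 2L)
        mate <- pop[[cand2[which.min(fit[cand2])]]]
        parent <- order_crossover(parent, mate)
      }
      nmut <- stats::rbinom(1L, N, mut_prob)
      if (nmut > 0) for (k in seq_len(nmut)) {
        ij <- sample.int(N, 2L)
        parent[ij] <- parent[rev(ij)]
      }
      newpop[[i]] <- parent
    }
    pop <- newpop
    fit <- vapply(pop, objective_of, 0)
    gen_best <- which.min(fit)
    if (fit[gen_best] < best_obj - 1e-12) {
      best_obj <- fit[gen_best]; best <- pop[[gen_best]]; stale <- 0L
    } else stale <- stale + 1L
  }
  list(best = best, objective = best_obj, iterations = it)
}

order_crossover <- function(p1, p2) {
  n <- length(p1)
  cut <- sort(sample.int(n, 2L))
  seg <- p1[cut[1L]:cut[2L]]
  rest <- p2[!(p2 %in% seg)]
  out <- integer(n)
  out[cut[1L]:cut[2L]] <- seg
  out[-(cut[1L]:cut[2L])] <- rest
  out
}
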