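#' Configure a centrality job
#'
#' A job bundles one network with a set of measures to compute, mirroring
#' a batch submission: input file (or \code{fixture:} pseudo-path),
#' format and directed/weighted/simplify flags, the measure list with
#' per-measure parameter overrides, an output workspace and a seed.
#'
#' @param input path to a network file, or \code{"fixture:<kind>[:n]"}
#'   (e.g. \code{"fixture:karate"}).
#' @param measures character vector of measure ids, or a named list
#'   mapping measure id to a parameter list.
#' @param output_dir workspace directory; each job gets a numbered
#'   subdirectory under \code{<output_dir>/jobs/}.
#' @param format,directed,weighted,simplify see [read_graph_file()].
#' @param description optional free-text job description.
#' @param seed integer; the RNG seed set before every measure, making
#'   stochastic measures reproducible.
#' @return a \code{job_config} object.
#' @export
job_config <- function(input, measures, output_dir,
                       format = "auto", directed = FALSE, weighted = FALSE,
                       simplify = TRUE, description = "", seed = 1) {
  if (is.character(measures))
    measures <- stats::setNames(replicate(length(measures), list()),
                                measures)
  if (is.null(names(measures)) || any(!nzchar(names(measures))))
    stop("measures must be named by measure id")
  structure(list(input = input, format = format, directed = directed,
                 weighted = weighted, simplify = simplify,
                 measures = measures, output_dir = output_dir,
                 description = description, seed = as.integer(seed)),
            class = "job_config")
}

#' Read a job configuration from a YAML file
#'
#' Flat keys matching the [job_config()] arguments; \code{measures} is
#' either a sequence of ids or a map id -> parameter map.
#'
#' @param path YAML file.
#' @param overrides named list of values that win over the file (the
#'   command-line layer).
#' @return a \code{job_config}.
#' @export
read_job_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  for (k in names(overrides)) y[[k]] <- overrides[[k]]
  need <- setdiff(c("input", "measures", "output_dir"), names(y))
  if (length(need)) stop("job config lacks field(s): ",
                         paste(need, collapse = ", "))
  meas <- y$measures
  if (!is.null(names(meas))) meas <- lapply(meas, function(p)
    if (is.null(p)) list() else p) else meas <- unlist(meas)
  job_config(y$input, meas, y$output_dir,
             format = y$format %||% "auto",
             directed = isTRUE(y$directed), weighted = isTRUE(y$weighted),
             simplify = !isFALSE(y$simplify),
             description = y$description %||% "", seed = y$seed %||% 1)
}

#' Run a centrality job
#'
#' Loads the network, computes every requested measure (setting the job
#' seed before each one), and writes into the job directory:
#' \code{scores.csv} (all successful measures), \code{scores.gml}
#' (score-annotated network) and \code{manifest.json} (config echo, seed,
#' per-measure status and timing).  A failing measure is recorded in the
#' manifest without aborting the rest.
#'
#' @param config a [job_config()].
#' @return a \code{job_record}: \code{job_id}, \code{status}
#'   (\code{"done"}, \code{"done-with-errors"} or \code{"failed"}),
#'   \code{dir}, \code{results} (list of [score_vector]s),
#'   \code{measure_status}, \code{paths}.
#' @examples
#' cfg <- job_config("fixture:path:3", c("degree", "closeness_freeman"),
#'                   output_dir = tempfile())
#' rec <- run_job(cfg)
#' rec$status
#' @export
run_job <- function(config) {
  stopifnot(inherits(config, "job_config"))
  jobs_root <- file.path(config$output_dir, "jobs")
  dir.create(jobs_root, recursive = TRUE, showWarnings = FALSE)
  job_id <- sprintf("%05d", length(list.dirs(jobs_root,
                                             recursive = FALSE)) + 1L)
  job_dir <- file.path(jobs_root, job_id)
  dir.create(job_dir)
  created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  g <- tryCatch({
    fx <- resolve_fixture_path(config$input)
    if (!is.null(fx)) fx else
      read_graph_file(config$input, config$format,
                      directed = config$directed,
                      weighted = config$weighted,
                      simplify = config$simplify)
  }, error = function(e) e)
  if (inherits(g, "error")) {
    manifest <- list(job_id = job_id, status = "failed", created = created,
                     error = conditionMessage(g), config = config_echo(config))
    jsonlite::write_json(manifest, file.path(job_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(structure(list(job_id = job_id, status = "failed", dir = job_dir,
                          results = list(), measure_status = list(),
                          paths = character(0)),
                     class = "job_record"))
  }

  results <- list()
  mstatus <- list()
  for (mid in names(config$measures)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      with_seed(config$seed,
                centrality_score(g, mid, config$measures[[mid]])),
      error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      mstatus[[mid]] <- list(status = "failed", seconds = round(dt, 3),
                             error = conditionMessage(res))
      message(sprintf("[job %s] %-28s FAILED (%.3fs): %s", job_id, mid, dt,
                      conditionMessage(res)))
    } else {
      results[[mid]] <- res
      mstatus[[mid]] <- list(status = "ok", seconds = round(dt, 3))
      message(sprintf("[job %s] %-28s ok     (%.3fs)", job_id, mid, dt))
    }
  }

  paths <- character(0)
  if (length(results)) {
    csv <- file.path(job_dir, "scores.csv")
    gml <- file.path(job_dir, "scores.gml")
    write_scores_csv(unname(results), csv, g = g)
    write_gml_annotated(g, unname(results), gml)
    paths <- c(scores_csv = csv, scores_gml = gml)
  }
  status <- if (!length(results)) "failed" else
    if (length(results) < length(config$measures)) "done-with-errors" else
      "done"
  manifest <- list(job_id = job_id, status = status, created = created,
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("netcentral")),
                   config = config_echo(config), measures = mstatus,
                   results = as.list(paths))
  jsonlite::write_json(manifest, file.path(job_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(job_id = job_id, status = status, dir = job_dir,
                 results = results, measure_status = mstatus,
                 paths = paths),
            class = "job_record")
}

#' @export
print.job_record <- function(x, ...) {
  cat("<job_record>", x$job_id, x$status, "-", length(x$results),
      "measure(s) in", x$dir, "\n")
  invisible(x)
}

config_echo <- function(config) {
  list(input = config$input, format = config$format,
       directed = config$directed, weighted = config$weighted,
       simplify = config$simplify, description = config$description,
       seed = config$seed,
       measures = lapply(config$measures, function(p)
         if (length(p)) p else structure(list(), names = character(0))))
}
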