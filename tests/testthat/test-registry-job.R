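# frozen roster: the calculable measures, one id per named index
MEASURE_ROSTER <- c(
  "alpha_centrality", "average_distance", "barycenter", "betweenness",
  "bonacich_power", "bottleneck", "bridging", "burt_constraint",
  "centroid_value", "closeness_dangalchev", "closeness_freeman",
  "closeness_latora", "closeness_vitality", "clusterrank",
  "communicability_betweenness", "community", "cross_clique",
  "current_flow_betweenness", "current_flow_closeness", "decay", "degree",
  "diffusion_degree", "dmnc", "eccentricity", "eigenvector", "entropy",
  "epc", "flow_betweenness", "geodesic_kpath", "graphlet_degree", "hits",
  "hubbell", "information", "katz", "kcore", "laplacian", "leaderrank",
  "leverage", "lin", "load", "lobby", "local_clustering", "markov", "mnc",
  "pagerank", "pairwise_disconnectivity", "radiality", "salsa",
  "semilocal", "strength", "stress", "subgraph",
  "topological_coefficient")

test_that("the registry matches the frozen 53-measure roster", {
  reg <- list_measures()
  expect_equal(nrow(reg), 53)
  expect_equal(sort(reg$id), MEASURE_ROSTER)
  expect_false(any(duplicated(reg$id)))
  expect_equal(reg$name, sort(reg$name))       # alphabetical listing
  expect_setequal(unique(reg$family),
                  c("distance", "neighborhood", "feedback", "flow",
                    "perturbation"))
  per <- list_measures("perturbation")
  expect_true(all(per$family == "perturbation"))
  expect_equal(nrow(per), 4)
  expect_error(centrality_score(make_fixture("path", n = 3),
                                "no_such_measure"), "unknown measure")
})

test_that("parameters are validated against descriptor ranges", {
  g <- make_fixture("path", n = 4)
  expect_error(centrality_score(g, "decay", list(delta = 2)),
               "out of range")
  expect_error(centrality_score(g, "decay", list(nope = 1)),
               "unknown parameter")
  expect_error(centrality_score(g, "dmnc", list(epsilon = 2.5)),
               "out of range")
})

test_that("run_job computes measures, writes outputs and records failures", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("a b", "b c"), p)
  ws <- tempfile()
  cfg <- job_config(p, c("degree", "closeness_freeman"), ws)
  rec <- suppressMessages(run_job(cfg))
  expect_equal(rec$status, "done")
  expect_equal(rec$job_id, "00001")
  df <- utils::read.csv(rec$paths[["scores_csv"]], check.names = FALSE)
  expect_equal(dim(df), c(3L, 3L))
  expect_equal(names(df), c("node", "degree", "closeness_freeman"))
  man <- jsonlite::read_json(file.path(rec$dir, "manifest.json"))
  expect_equal(man$status, "done")
  expect_equal(man$measures$degree$status, "ok")

  # unknown measure: job completes with a per-measure failure
  cfg2 <- job_config(p, c("degree", "no_such_measure"), ws)
  rec2 <- suppressMessages(run_job(cfg2))
  expect_equal(rec2$job_id, "00002")
  expect_equal(rec2$status, "done-with-errors")
  expect_equal(rec2$measure_status$no_such_measure$status, "failed")
  expect_named(rec2$results, "degree")

  # unreadable input: failed record, no exception
  cfg3 <- job_config(tempfile(fileext = ".gml"), "degree", ws)
  rec3 <- suppressMessages(run_job(cfg3))
  expect_equal(rec3$status, "failed")
})

test_that("repeated seeded runs are byte-identical", {
  ws1 <- tempfile(); ws2 <- tempfile()
  mk <- function(ws) suppressMessages(run_job(job_config(
    "fixture:karate", list(degree = list(),
                           epc = list(samples = 200, seed = 9),
                           pagerank = list()),
    ws, seed = 4)))
  r1 <- mk(ws1); r2 <- mk(ws2)
  expect_identical(readLines(r1$paths[["scores_csv"]]),
                   readLines(r2$paths[["scores_csv"]]))
  expect_identical(readLines(r1$paths[["scores_gml"]]),
                   readLines(r2$paths[["scores_gml"]]))
})

test_that("YAML job configs load with CLI-style overrides", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("input: fixture:path:4",
               "output_dir: somewhere",
               "seed: 7",
               "measures:",
               "  degree:",
               "  decay:",
               "    delta: 0.25"), yml)
  cfg <- read_job_config(yml, overrides = list(output_dir = tempfile()))
  expect_equal(names(cfg$measures), c("degree", "decay"))
  expect_equal(cfg$measures$decay$delta, 0.25)
  expect_equal(cfg$seed, 7L)
  rec <- suppressMessages(run_job(cfg))
  expect_equal(rec$status, "done")
  sc <- utils::read.csv(rec$paths[["scores_csv"]], check.names = FALSE)
  expect_equal(sc$decay,
               unname(scores_of(make_fixture("path", n = 4), "decay",
                                list(delta = 0.25))),
               tolerance = 1e-10)
})

test_that("the command-line interface runs end to end", {
  cli <- system.file("cli", "netcentral", package = "netcentral")
  skip_if(cli == "", "CLI script not installed")
  rsc <- file.path(R.home("bin"), "Rscript")
  out <- system2(rsc, c(cli, "measures"), stdout = TRUE)
  expect_true(any(grepl("betweenness", out)))
  ws <- tempfile()
  st <- system2(rsc, c(cli, "run", "--input", "fixture:star:6",
                       "--measures", "degree,betweenness",
                       "--output", ws, "--seed", "3"),
                stdout = TRUE, stderr = TRUE)
  expect_equal(attr(st, "status"), NULL)   # exit 0
  csv <- file.path(ws, "jobs", "00001", "scores.csv")
  expect_true(file.exists(csv))
  ess <- tempfile(); writeLines(c("v1", "v2"), ess)
  en <- system2(rsc, c(cli, "enrich", "--scores", csv, "--measure",
                       "degree", "--essential", ess, "--k", "2"),
                stdout = TRUE)
  expect_true(grepl("enrichment", en[1]))
  ag <- system2(rsc, c(cli, "aggregate", "--scores", csv, "--seed", "2"),
                stdout = TRUE)
  expect_true(any(grepl("objective", ag)))
})
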