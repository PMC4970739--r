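test_that("the full pipeline produces coherent base-case output", {
  run <- suppressMessages(evaluate_cea(default_config(), test_curves()))
  expect_named(run$results, c("strategy", "cost", "effect"))
  expect_true(all(run$results$cost > 0))
  expect_true(all(run$results$effect > 0 & run$results$effect < 5))
  expect_equal(run$comparison$intervention, "testing")
  expect_equal(nrow(run$fit_report) %% 2, 0)
  expect_match(run$config_hash, "^[0-9a-f]+$")
  # five-year horizon, all branches extrapolated across it
  expect_true(all(vapply(run$fit_report$scale, is.finite, logical(1))))
})

test_that("missing curve sets are reported by branch id", {
  curves <- test_curves()
  curves[["os_bsc"]] <- NULL
  expect_error(evaluate_cea(default_config(), curves), "os_bsc")
})

test_that("an empty override reproduces the base case exactly", {
  curves <- test_curves()
  base <- suppressMessages(evaluate_cea(default_config(), curves))
  same <- suppressMessages(run_scenario(default_config(), curves, list()))
  expect_equal(same$results, base$results, tolerance = 1e-12)
  expect_identical(same$config_hash, base$config_hash)
})

test_that("single-method extrapolations bracket the mean-of-methods base case", {
  curves <- test_curves()
  base <- suppressMessages(evaluate_cea(default_config(), curves))
  reg <- suppressMessages(run_scenario(default_config(), curves,
                                       "extrapolation_regression"))
  ls <- suppressMessages(run_scenario(default_config(), curves,
                                      "extrapolation_least_squares"))
  for (i in 1:2) {
    lo <- pmin(reg$results$effect[i], ls$results$effect[i])
    hi <- pmax(reg$results$effect[i], ls$results$effect[i])
    expect_gte(base$results$effect[i], lo - 1e-9)
    expect_lte(base$results$effect[i], hi + 1e-9)
  }
})

test_that("utility scenarios lower QALYs in both strategies", {
  curves <- test_curves()
  base <- suppressMessages(evaluate_cea(default_config(), curves))
  for (sc in c("ae_whole_period", "iv_disutility")) {
    res <- suppressMessages(run_scenario(default_config(), curves, sc))
    expect_true(all(res$results$effect < base$results$effect))
    # costs are untouched by utility scenarios
    expect_equal(res$results$cost, base$results$cost, tolerance = 1e-9)
  }
})

test_that("the OS-substitution scenario raises survival-driven cost and effect", {
  curves <- test_curves()
  base <- suppressMessages(evaluate_cea(default_config(), curves))
  sub <- suppressMessages(run_scenario(default_config(), curves,
                                       "os_substitution"))
  i <- which(sub$results$strategy == "testing")
  # binding first-line TKI OS to the longer chemo-doublet OS keeps patients
  # alive (and on therapy) longer: both cost and QALYs rise for testing
  expect_gt(sub$results$cost[i], base$results$cost[i])
  expect_gt(sub$results$effect[i], base$results$effect[i])
  # the no-testing strategy is untouched
  j <- which(sub$results$strategy == "no testing")
  expect_equal(sub$results$cost[j], base$results$cost[j], tolerance = 1e-9)
})

test_that("unknown scenarios and override keys are rejected", {
  curves <- test_curves()
  expect_error(run_scenario(default_config(), curves, "no_such"), "available")
  expect_error(run_scenario(default_config(), curves, list(bogus = 1)),
               "valid keys")
})

test_that("the report embeds the configuration hash and the results", {
  dir <- withr::local_tempdir()
  run <- suppressMessages(evaluate_cea(default_config(), test_curves()))
  path <- file.path(dir, "report.txt")
  cea_report(run, path)
  txt <- readLines(path)
  expect_true(any(grepl(run$config_hash, txt, fixed = TRUE)))
  expect_true(any(grepl("testing", txt)))
  expect_true(any(grepl("least_squares", txt)))
})

test_that("the command-line wrapper runs end to end", {
  cli <- system.file("cli.R", package = "ceadx")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cli, "simulate", "--out", shQuote(dir),
                            "--seed", "4"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  out2 <- system2(rscript, c(cli, "run",
                             "--config", shQuote(file.path(dir, "config.yaml")),
                             "--manifest", shQuote(file.path(dir, "manifest.yaml")),
                             "--out", shQuote(file.path(dir, "results"))),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "results", "results.csv")))
  res <- read.csv(file.path(dir, "results", "results.csv"))
  expect_equal(sort(res$strategy), sort(c("testing", "no testing")))
})
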