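test_that("the product-limit estimate steps by 1/n without censoring", {
  cv <- simulate_km(sim_spec("nc", shape = 1.5, scale = 8, n = 40,
                             censor_rate = 0, cutoff = Inf, seed = 2))
  ev <- attr(cv, "events")
  expect_equal(sum(ev$n_event), 40)
  # continuous event times: all distinct, so each step is exactly 1/40
  drops <- -diff(c(1, cv$surv[cv$time > 0]))
  expect_equal(drops, rep(1 / 40, length(drops)), tolerance = 1e-12)
})

test_that("fully censored data give a flat curve with a warning", {
  expect_warning(
    cv <- simulate_km(sim_spec("cens", shape = 1.5, scale = 100, n = 20,
                               censor_rate = 0, cutoff = 0.001, seed = 3)),
    "censored"
  )
  expect_equal(step_surv(cv, c(0, 5, 50)), c(1, 1, 1))
})

test_that("simulation is deterministic under a fixed seed", {
  spec <- sim_spec("det", shape = 1.3, scale = 9, n = 100,
                   censor_rate = 0.02, cutoff = 30, seed = 99)
  a <- simulate_km(spec)
  b <- simulate_km(spec)
  expect_identical(a$time, b$time)
  expect_identical(a$surv, b$surv)

  c1 <- synthetic_curves(5)
  c2 <- synthetic_curves(5)
  expect_identical(c1, c2)
  c3 <- synthetic_curves(6)
  expect_false(identical(c1, c3))
})

test_that("fitting simulated data recovers the generating parameters", {
  cv <- simulate_km(sim_spec("rec", shape = 1.5, scale = 8, n = 300,
                             censor_rate = 0, cutoff = Inf, seed = 11))
  fit <- fit_regression(cv)
  expect_lt(abs(fit$shape - 1.5) / 1.5, 0.10)
  expect_lt(abs(fit$scale - 8) / 8, 0.10)

  # median recovery over replicates at n = 500
  fits <- vapply(1:50, function(i) {
    cvi <- simulate_km(sim_spec("r", shape = 1.5, scale = 8, n = 500,
                                censor_rate = 0.01, cutoff = 30,
                                seed = 1000 + i))
    f <- fit_regression(cvi)
    c(f$shape, f$scale)
  }, numeric(2))
  expect_lt(abs(median(fits[1, ]) - 1.5) / 1.5, 0.05)
  expect_lt(abs(median(fits[2, ]) - 8) / 8, 0.05)
})

test_that("pooling identical-parameter trials converges to the truth", {
  truth <- function(t) exp(-(t / 10)^1.4)
  err <- vapply(c(60, 1000), function(n) {
    curves <- lapply(1:4, function(i) {
      simulate_km(sim_spec(paste0("t", i), shape = 1.4, scale = 10, n = n,
                           censor_rate = 0, cutoff = 30, seed = 400 + i))
    })
    pooled <- pool_curves(curves)
    tt <- seq(1, 20, by = 1)
    max(abs(step_surv(pooled, tt) - truth(tt)))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("the synthetic study has the multi-trial pooling structure", {
  curves <- test_curves()
  expect_length(curves[["pfs_ert1_mpos"]], 3)
  expect_length(curves[["pfs_ert2_all"]], 12)
  expect_length(curves[["os_cgem1_all"]], 9)
  expect_length(curves[["os_cpem1_all"]], 2)
  # TKI PFS in mutation-positive patients clearly dominates chemo PFS
  tki <- pool_curves(curves[["pfs_ert1_mpos"]])
  chemo <- pool_curves(curves[["pfs_cpem1_mneg"]])
  tt <- 3:18
  expect_true(all(step_surv(tki, tt) > step_surv(chemo, tt)))
})

test_that("the on-disk fixture loads and the pipeline runs from files", {
  dir <- withr::local_tempdir()
  paths <- synthetic_fixture(dir, seed = 3)
  expect_true(file.exists(paths$config))
  expect_true(file.exists(paths$manifest))
  config <- load_config(paths$config)
  curve_sets <- read_curve_manifest(paths$manifest)
  expect_length(curve_sets[["pfs_ert2_all"]], 12)
  run <- suppressMessages(evaluate_cea(config, curve_sets))
  expect_s3_class(run, "cea_run")
  # directional check: the testing strategy is more effective
  expect_gt(run$results$effect[run$results$strategy == "testing"],
            run$results$effect[run$results$strategy == "no testing"])
  # scenario overrides parse from disk
  ov <- yaml::read_yaml(file.path(paths$scenario_dir, "ae_whole_period.yaml"))
  expect_true(isTRUE(ov$ae_whole_period))
})
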