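#' Fit every survival branch referenced by a configuration
#'
#' Pools each branch's trial curves by sample size and fits the Weibull
#' extrapolation by both methods, keeping the model the configured
#' `extrapolation` selects ("mean" of the two by default).
#'
#' @param config a validated configuration (see [default_config()]).
#' @param curves named list of curve sets: for each branch id, a list of
#'   [survival_curve] objects.
#' @return named list of [fit_branch()] results for every branch the
#'   pathways and `bsc_curve` reference.
#' @export
fit_branches <- function(config, curves) {
  ids <- unique(c(
    unlist(lapply(config$pathways, function(pw)
      lapply(pw, function(ln) c(ln$pfs, ln$os)))),
    config$bsc_curve
  ))
  missing <- setdiff(ids, names(curves))
  if (length(missing)) {
    stop("no curve set supplied for branch(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  setNames(
    lapply(ids, function(id) fit_branch(curves[[id]], config$extrapolation)),
    ids
  )
}

build_line <- function(binding, position, config, schedules, is_last = FALSE) {
  rg <- binding$regimen
  cost <- config$costs[[rg]]
  ut <- config$utilities
  utility <- if (position == 1L) ut$pre_progression else ut$post_progression
  oral <- rg %in% config$oral_regimens
  treatment_line(
    label = paste0(rg, "_L", position),
    pfs = schedules[[binding$pfs]],
    os = schedules[[binding$os]],
    cost_admin = cost$admin, cost_nonadmin = cost$nonadmin,
    admin_cycles = cost$admin_cycles,
    utility = utility,
    is_oral = oral,
    ae_disutility = config$ae_burden[[rg]],
    ae_whole_period = isTRUE(config$ae_whole_period),
    oral_adjustment = ut$oral_adjustment,
    iv_disutility = if (isTRUE(ut$iv_disutility_applied) && !oral)
      ut$iv_disutility else 0
  )
}

build_bsc_line <- function(config, schedules) {
  cost <- config$costs$bsc
  treatment_line(
    label = "bsc",
    pfs = NULL,
    os = schedules[[config$bsc_curve]],
    cost_admin = cost$admin, cost_nonadmin = cost$nonadmin,
    admin_cycles = cost$admin_cycles,
    utility = config$utilities$bsc,
    is_oral = FALSE,
    ae_disutility = config$ae_burden$bsc %||% 0
  )
}

build_pathway <- function(name, config, schedules) {
  bindings <- config$pathways[[name]]
  lines <- lapply(seq_along(bindings), function(i)
    build_line(bindings[[i]], i, config, schedules))
  c(lines, list(build_bsc_line(config, schedules)))
}

#' Build the two strategies from a configuration
#'
#' The testing strategy mixes the test-positive pathway (true plus false
#' positives) with the test-negative pathway (true and false negatives plus
#' unknown results, all routed to chemotherapy) at the decision-tree branch
#' proportions, and carries the diagnostic test cost. The no-testing
#' strategy is the single conventional-chemotherapy pathway at no test
#' cost.
#'
#' @inheritParams fit_branches
#' @param fits optional precomputed [fit_branches()] result.
#' @return list with elements `testing` and `no_testing`
#'   ([strategy_definition()]s), `proportions`, `fits` and `schedules`.
#' @export
build_strategies <- function(config, curves, fits = NULL) {
  validate_config(config)
  if (is.null(fits)) fits <- fit_branches(config, curves)
  H <- config$cycles$horizon
  schedules <- lapply(fits, to_transition_schedule, horizon = H)
  ep <- config$epidemiology
  bp <- branch_proportions(
    ep$prevalence,
    test_performance(ep$sensitivity, ep$specificity, ep$p_unknown)
  )
  testing <- strategy_definition(
    "testing",
    arms = list(
      list(weight = bp$p_test_positive,
           lines = build_pathway("test_positive", config, schedules)),
      list(weight = bp$p_test_negative + bp$p_unknown,
           lines = build_pathway("test_negative", config, schedules))
    ),
    test_cost = config$test_cost
  )
  no_testing <- strategy_definition(
    "no testing",
    arms = list(
      list(weight = 1, lines = build_pathway("no_testing", config, schedules))
    ),
    test_cost = 0
  )
  list(testing = testing, no_testing = no_testing,
       proportions = bp, fits = fits, schedules = schedules)
}

#' Run the full cost-effectiveness analysis
#'
#' Fits and extrapolates every survival branch, builds the testing and
#' no-testing strategies, runs the cohort model for each, and compares them
#' (testing as the intervention).
#'
#' @inheritParams build_strategies
#' @return An object of class `cea_run`: list with `results` (data frame of
#'   strategy, cost, effect), `comparison` ([compare_strategies()]),
#'   `proportions`, `fit_report`, `config`, `config_hash`, and the two
#'   [ce_result()]s in `ce`.
#' @export
evaluate_cea <- function(config = default_config(), curves, fits = NULL) {
  built <- build_strategies(config, curves, fits)
  cfg_cycles <- cycle_config(
    horizon = config$cycles$horizon,
    annual_discount_rate = config$cycles$annual_discount_rate,
    half_cycle_correction = isTRUE(config$cycles$half_cycle_correction)
  )
  ce_test <- evaluate_strategy(built$testing, cfg_cycles)
  ce_none <- evaluate_strategy(built$no_testing, cfg_cycles)
  structure(
    list(
      results = data.frame(
        strategy = c(ce_test$strategy, ce_none$strategy),
        cost = c(ce_test$cost, ce_none$cost),
        effect = c(ce_test$effect, ce_none$effect)
      ),
      comparison = compare_strategies(ce_test, ce_none),
      ce = list(testing = ce_test, no_testing = ce_none),
      proportions = built$proportions,
      fit_report = fit_report(built$fits),
      config = config,
      config_hash = config_hash(config)
    ),
    class = "cea_run"
  )
}

#' @export
print.cea_run <- function(x, ...) {
  cat("<cea_run> config", x$config_hash, "\n")
  df <- x$results
  df$cost <- round(df$cost)
  df$effect <- round(df$effect, 5)
  print(df, row.names = FALSE)
  cat(sprintf("testing vs no testing: %s (incr cost %.0f, incr effect %.5f)\n",
              x$comparison$verdict, x$comparison$incr_cost,
              x$comparison$incr_effect))
  invisible(x)
}

#' Scenario analyses
#'
#' `scenario_registry()` returns the named configuration overrides for the
#' shipped scenario analyses:
#' \describe{
#'   \item{extrapolation_regression}{extrapolate with the log-log
#'     regression fit only}
#'   \item{extrapolation_least_squares}{extrapolate with the least-squares
#'     fit only}
#'   \item{os_substitution}{bind first-line erlotinib OS to the pooled
#'     first-line cisplatin+pemetrexed OS of all patients (a longer OS
#'     than the base-case cisplatin+gemcitabine binding)}
#'   \item{ert_pem}{second-line pemetrexed instead of
#'     cisplatin+pemetrexed in mutation-positive patients}
#'   \item{cgem_pem}{first-line cisplatin+gemcitabine and second-line
#'     pemetrexed for the chemotherapy pathways (mutation-negative and
#'     no-testing)}
#'   \item{ae_whole_period}{adverse-event disutility applied over the whole
#'     administration period instead of the entry cycle only}
#'   \item{iv_disutility}{per-cycle disutility for intravenous
#'     administration during chemotherapy}
#' }
#' `run_scenario()` deep-merges overrides into the configuration
#' (validating the keys) and re-runs the full pipeline.
#'
#' @param config base configuration.
#' @param curves named list of curve sets (see [fit_branches()]).
#' @param overrides named list of configuration overrides, or a scenario
#'   name from `scenario_registry()`.
#' @return `run_scenario()` returns a `cea_run`; `scenario_registry()` a
#'   named list of override lists.
#' @export
run_scenario <- function(config, curves, overrides = list()) {
  if (is.character(overrides)) {
    reg <- scenario_registry()
    if (!overrides %in% names(reg)) {
      stop("unknown scenario '", overrides, "'; available: ",
           paste(names(reg), collapse = ", "), call. = FALSE)
    }
    overrides <- reg[[overrides]]
  }
  config <- merge_config(config, overrides)
  evaluate_cea(config, curves)
}

#' @rdname run_scenario
#' @export
scenario_registry <- function() {
  list(
    extrapolation_regression = list(extrapolation = "regression"),
    extrapolation_least_squares = list(extrapolation = "least_squares"),
    os_substitution = list(
      pathways = list(
        test_positive = list(
          list(regimen = "ert",  pfs = "pfs_ert1_mpos",  os = "os_cpem1_all"),
          list(regimen = "cpem", pfs = "pfs_cpem2_mpos", os = "os_cpem2_mpos")
        )
      )
    ),
    ert_pem = list(
      pathways = list(
        test_positive = list(
          list(regimen = "ert", pfs = "pfs_ert1_mpos", os = "os_cgem1_all"),
          list(regimen = "pem", pfs = "pfs_pem2",      os = "os_pem2")
        )
      )
    ),
    cgem_pem = list(
      pathways = list(
        test_negative = list(
          list(regimen = "cgem", pfs = "pfs_cgem1_all", os = "os_cgem1_all"),
          list(regimen = "pem",  pfs = "pfs_pem2",      os = "os_pem2")
        ),
        no_testing = list(
          list(regimen = "cgem", pfs = "pfs_cgem1_all", os = "os_cgem1_all"),
          list(regimen = "ert",  pfs = "pfs_ert2_all",  os = "os_ert2_all")
        )
      )
    ),
    ae_whole_period = list(ae_whole_period = TRUE),
    iv_disutility = list(utilities = list(iv_disutility_applied = TRUE))
  )
}

#' One-way sensitivity analysis over the shipped parameter set
#'
#' Perturbs each parameter to its low and high value, re-runs the full
#' pipeline, and tabulates the swing of the summary statistic
#' ([tornado_analysis()]). Cost parameters default to +/- 25% around base;
#' epidemiological parameters and the horizon use explicit ranges.
#'
#' @param config base configuration.
#' @param curves named list of curve sets.
#' @param params optional data frame (`name`, `low`, `high`) overriding
#'   [default_tornado_params()]. Names are configuration paths
#'   (dot-separated); `costs.<regimen>` scales both phase costs of the
#'   regimen by the given multiplier.
#' @param wtp willingness-to-pay threshold used when the summary statistic
#'   is the incremental net monetary benefit.
#' @return A [tornado_analysis()] result.
#' @export
cea_tornado <- function(config, curves, params = NULL, wtp = 30000) {
  validate_config(config)
  if (is.null(params)) params <- default_tornado_params(config)
  fits <- fit_branches(config, curves)  # reused when curves are unaffected
  eval_fn <- function(name, value) {
    if (is.null(name)) {
      return(evaluate_cea(config, curves, fits = fits)$comparison)
    }
    cfg <- apply_tornado_param(config, name, value)
    evaluate_cea(cfg, curves, fits = fits)$comparison
  }
  tornado_analysis(eval_fn, params, wtp = wtp)
}

apply_tornado_param <- function(config, name, value) {
  if (grepl("^costs\\.[a-z]+$", name)) {
    rg <- sub("^costs\\.", "", name)
    if (!rg %in% names(config$costs)) {
      stop("unknown regimen in tornado parameter '", name, "'", call. = FALSE)
    }
    config$costs[[rg]]$admin <- config$costs[[rg]]$admin * value
    config$costs[[rg]]$nonadmin <- config$costs[[rg]]$nonadmin * value
    return(config)
  }
  set_by_path(config, name, value)
}

#' @rdname cea_tornado
#' @export
default_tornado_params <- function(config) {
  cost_regimens <- c("ert", "cpem", "dox", "bsc")
  rows <- list(
    data.frame(name = paste0("costs.", cost_regimens), low = 0.75, high = 1.25),
    data.frame(name = "test_cost",
               low = config$test_cost * 0.75, high = config$test_cost * 1.25),
    data.frame(name = "epidemiology.prevalence", low = 0.2, high = 0.5),
    data.frame(name = "epidemiology.p_unknown", low = 0.015, high = 0.2),
    data.frame(name = "epidemiology.sensitivity", low = 0.9, high = 1.0),
    data.frame(name = "cycles.horizon", low = 36, high = 60)
  )
  do.call(rbind, rows)
}

#' Plain-text report of a cost-effectiveness run
#'
#' @param run a `cea_run`.
#' @param path optional file to write to.
#' @return The report lines, invisibly (always); written to `path` when
#'   given.
#' @export
cea_report <- function(run, path = NULL) {
  stopifnot(inherits(run, "cea_run"))
  cmp <- run$comparison
  lines <- c(
    "Cost-effectiveness report",
    paste0("configuration hash: ", run$config_hash),
    "",
    sprintf("%-12s %12s %12s", "strategy", "cost (USD)", "QALY"),
    sprintf("%-12s %12.0f %12.5f", run$results$strategy, run$results$cost,
            run$results$effect),
    "",
    sprintf("incremental cost (testing - no testing): %.2f", cmp$incr_cost),
    sprintf("incremental effect: %.5f QALY", cmp$incr_effect),
    sprintf("verdict: %s", cmp$verdict),
    "",
    "fitted survival models:",
    utils::capture.output(print(run$fit_report, row.names = FALSE))
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
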