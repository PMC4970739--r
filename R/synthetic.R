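#' Specification for one simulated trial arm
#'
#' Ground truth for the Kaplan-Meier simulator: event times are Weibull,
#' censoring is the minimum of an independent exponential dropout time and
#' an administrative follow-up cutoff.
#'
#' @param label curve label.
#' @param shape,scale true Weibull parameters (months).
#' @param n number of patients (>= 2).
#' @param censor_rate exponential dropout rate per month (>= 0; 0 disables
#'   dropout).
#' @param cutoff administrative censoring time in months (> 0; may be
#'   `Inf`).
#' @param seed optional integer seed making the simulation reproducible.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(label, shape, scale, n, censor_rate = 0, cutoff = Inf,
                     seed = NULL) {
  stopifnot(shape > 0, scale > 0, n >= 2, n == round(n),
            censor_rate >= 0, cutoff > 0)
  structure(list(label = label, shape = shape, scale = scale, n = as.integer(n),
                 censor_rate = censor_rate, cutoff = cutoff, seed = seed),
            class = "sim_spec")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a Kaplan-Meier curve with known ground truth
#'
#' Draws Weibull event times and independent censoring per [sim_spec()],
#' computes the product-limit estimate, and returns it as a
#' [survival_curve] (points with positive survival at event times). The
#' underlying event table (time, at risk, events, censored) is attached as
#' attribute `events`; attribute `truth` carries the generating parameters.
#'
#' @param spec a [sim_spec()].
#' @return A [survival_curve]. If every observation is censored before the
#'   first event the curve is flat at 1 and a warning is issued.
#' @examples
#' cv <- simulate_km(sim_spec("toy", shape = 1.5, scale = 8, n = 50, seed = 42))
#' fit_regression(cv)
#' @export
simulate_km <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    event_t <- rweibull(spec$n, spec$shape, spec$scale)
    cens_t <- if (spec$censor_rate > 0) {
      pmin(rexp(spec$n, spec$censor_rate), spec$cutoff)
    } else {
      rep(spec$cutoff, spec$n)
    }
    obs <- pmin(event_t, cens_t)
    status <- as.integer(event_t <= cens_t)
  })
  if (sum(status) == 0) {
    warning("all observations censored before the first event; ",
            "returning a flat curve (label '", spec$label, "')")
    out <- survival_curve(spec$label, numeric(0), numeric(0), n = spec$n)
  } else {
    km <- survival::survfit(survival::Surv(obs, status) ~ 1)
    keep <- km$n.event > 0 & km$surv > 0
    out <- survival_curve(spec$label, km$time[keep], km$surv[keep], n = spec$n)
    attr(out, "events") <- data.frame(
      time = km$time, n_risk = km$n.risk,
      n_event = km$n.event, n_censor = km$n.censor
    )
  }
  attr(out, "truth") <- spec
  out
}

# Synthetic ground truth per model branch. Shapes/scales are package
# inventions chosen so medians sit where a practitioner would expect them
# for these regimens — in particular first-line TKI PFS in mutation-positive
# patients is far longer than chemotherapy PFS — and trial counts per branch
# match the pooling structure the pipeline must handle. None of these
# numbers are published trial data.
synthetic_truth <- function() {
  df <- read.csv(text = "
id,shape,scale,n_trials,cutoff
pfs_ert1_mpos,1.6,16.3,3,30
pfs_cpem2_mpos,1.2,5.4,1,24
pfs_cpem1_mneg,1.3,6.6,1,24
pfs_dox2_mneg,1.1,4.2,1,24
pfs_cpem1_all,1.3,7.3,2,24
pfs_ert2_all,1.0,4.3,12,24
pfs_cgem1_all,1.3,6.6,9,24
pfs_pem2,1.2,4.8,1,24
os_cgem1_all,1.4,14.3,9,36
os_cpem2_mpos,1.3,13.3,1,36
os_cpem1_all,1.4,16.2,2,36
os_dox2_mneg,1.2,10.9,1,36
os_ert2_all,1.2,11.5,12,36
os_pem2,1.2,11.5,1,36
os_bsc,1.3,6.0,1,24
", stringsAsFactors = FALSE)
  df
}

#' Generate the synthetic curve sets for a full pipeline run
#'
#' Builds one set of simulated, monthly-digitized Kaplan-Meier curves per
#' model branch, with the multi-trial pooling structure of the base-case
#' model (e.g. three trials behind first-line TKI PFS in mutation-positive
#' patients and twelve behind second-line TKI in unselected patients).
#' Trial sample sizes are drawn between 80 and 400; censoring combines 2%
#' monthly dropout with each branch's administrative cutoff. Identical
#' seeds give identical output.
#'
#' @param seed integer seed.
#' @param censor_rate monthly exponential dropout rate.
#' @return Named list of curve sets (branch id -> list of
#'   [survival_curve]), with the ground-truth table as attribute `truth`.
#' @export
synthetic_curves <- function(seed = 1, censor_rate = 0.02) {
  truth <- synthetic_truth()
  base_seed <- (as.integer(seed) %% 100000L) * 10000L
  counter <- 0L
  curves <- setNames(vector("list", nrow(truth)), truth$id)
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    set <- vector("list", row$n_trials)
    for (j in seq_len(row$n_trials)) {
      counter <- counter + 1L
      n <- with_seed(base_seed + counter, sample(80:400, 1))
      counter <- counter + 1L
      spec <- sim_spec(sprintf("%s_trial%d", row$id, j),
                       shape = row$shape, scale = row$scale, n = n,
                       censor_rate = censor_rate, cutoff = row$cutoff,
                       seed = base_seed + counter)
      set[[j]] <- digitize_monthly(simulate_km(spec))
    }
    curves[[row$id]] <- set
  }
  attr(curves, "truth") <- truth
  curves
}

#' Write a complete synthetic study to disk
#'
#' Emits everything a from-files pipeline run needs: one CSV per simulated
#' trial curve under `curves/`, a YAML manifest mapping branches to files,
#' the base-case configuration as `config.yaml`, and one override file per
#' scenario under `scenarios/`. All values are synthetic (see
#' [synthetic_curves()]).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed passed to [synthetic_curves()].
#' @return Invisibly, a list with the paths (`config`, `manifest`,
#'   `scenario_dir`, `curve_dir`).
#' @export
synthetic_fixture <- function(dir, seed = 1) {
  curve_dir <- file.path(dir, "curves")
  scen_dir <- file.path(dir, "scenarios")
  for (d in c(dir, curve_dir, scen_dir)) {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  }
  curves <- synthetic_curves(seed)
  manifest <- lapply(names(curves), function(id) {
    vapply(seq_along(curves[[id]]), function(j) {
      fn <- sprintf("%s_trial%d.csv", id, j)
      write_survival_curve(curves[[id]][[j]], file.path(curve_dir, fn))
      file.path("curves", fn)
    }, character(1))
  })
  names(manifest) <- names(curves)
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(lapply(manifest, as.list), manifest_path)
  config_path <- file.path(dir, "config.yaml")
  write_config(default_config(), config_path)
  for (nm in names(scenario_registry())) {
    yaml::write_yaml(scenario_registry()[[nm]],
                     file.path(scen_dir, paste0(nm, ".yaml")))
  }
  invisible(list(config = config_path, manifest = manifest_path,
                 scenario_dir = scen_dir, curve_dir = curve_dir))
}
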