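# Shared fixtures, built once per test run.

# full synthetic curve library (all model branches)
test_curves <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suppressMessages(synthetic_curves(seed = 7))
    cache
  }
})

# raw transition schedule from explicit probabilities (toy models)
toy_schedule <- function(probs) {
  structure(list(probs = probs, horizon = length(probs)),
            class = "transition_schedule")
}

# a minimal treatment line over toy schedules
toy_line <- function(label = "line", pfs = NULL, p_death, H = length(p_death),
                     cost_admin = 0, cost_nonadmin = cost_admin,
                     admin_cycles = Inf, utility = 0.5, ...) {
  treatment_line(
    label,
    pfs = if (!is.null(pfs)) toy_schedule(rep_len(pfs, H)),
    os = toy_schedule(rep_len(p_death, H)),
    cost_admin = cost_admin, cost_nonadmin = cost_nonadmin,
    admin_cycles = admin_cycles, utility = utility, ...
  )
}

# single-pathway strategy ending in a BSC-style line
toy_strategy <- function(lines, test_cost = 0, name = "toy") {
  strategy_definition(name, arms = list(list(weight = 1, lines = lines)),
                      test_cost = test_cost)
}

# exact Weibull survival points (no noise)
weibull_points <- function(shape, scale, t = 1:12, label = "exact", n = 100) {
  survival_curve(label, t, exp(-(t / scale)^shape), n = n)
}

# iteratively refined grid search minimizing the log-log regression
# residual; independent oracle for fit_regression
grid_regression_oracle <- function(curve, rounds = 7, pts = 81) {
  use <- curve$time > 0 & curve$surv < 1 & curve$surv > 0
  x <- log(curve$time[use])
  y <- log(-log(curve$surv[use]))
  obj <- function(shape, scale) sum((y - shape * (x - log(scale)))^2)
  lo <- c(0.2, 1); hi <- c(5, 60)
  best <- NULL
  for (r in seq_len(rounds)) {
    ss <- seq(lo[1], hi[1], length.out = pts)
    sc <- seq(lo[2], hi[2], length.out = pts)
    vals <- outer(ss, sc, Vectorize(obj))
    ij <- arrayInd(which.min(vals), dim(vals))
    best <- c(ss[ij[1]], sc[ij[2]])
    step <- c(ss[2] - ss[1], sc[2] - sc[1])
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  list(shape = best[1], scale = best[2], value = obj(best[1], best[2]))
}

# coarse grid minimum of the survival-scale least-squares objective
grid_ls_oracle <- function(curve, n_grid = 200,
                           shape_range = c(0.2, 5), scale_range = c(1, 60)) {
  ss <- seq(shape_range[1], shape_range[2], length.out = n_grid)
  sc <- seq(scale_range[1], scale_range[2], length.out = n_grid)
  obj <- function(shape, scale) {
    sum((curve$surv - exp(-(curve$time / scale)^shape))^2)
  }
  vals <- outer(ss, sc, Vectorize(obj))
  ij <- arrayInd(which.min(vals), dim(vals))
  list(shape = ss[ij[1]], scale = sc[ij[2]], value = min(vals))
}

ls_sse <- function(curve, model) {
  sum((curve$surv - surv_prob(model, curve$time))^2)
}
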