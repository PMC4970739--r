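#' Weibull survival model
#'
#' Parametric survival function S(t) = exp(-(t/scale)^shape) used to
#' extrapolate digitized Kaplan-Meier curves beyond follow-up. The shape is
#' dimensionless; the scale is in months. shape = 1 recovers the
#' exponential model.
#'
#' @param shape positive shape parameter.
#' @param scale positive scale parameter (months).
#' @return An object of class `weibull_model`.
#' @export
weibull_model <- function(shape, scale) {
  stopifnot(is.numeric(shape), is.numeric(scale), length(shape) == 1L,
            length(scale) == 1L)
  if (!is.finite(shape) || shape <= 0) stop("`shape` must be > 0", call. = FALSE)
  if (!is.finite(scale) || scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  structure(list(shape = shape, scale = scale), class = "weibull_model")
}

#' @export
print.weibull_model <- function(x, ...) {
  cat(sprintf("<weibull_model> shape = %.6g, scale = %.6g months (median %.3g)\n",
              x$shape, x$scale, x$scale * log(2)^(1 / x$shape)))
  invisible(x)
}

#' Evaluate a survival function
#'
#' Generic accessor S(t) for the model objects used by the pipeline:
#' parametric Weibull fits, their pointwise average, and raw step curves.
#'
#' @param model a `weibull_model`, `averaged_survival` or `survival_curve`.
#' @param t numeric vector of times in months (>= 0).
#' @return numeric vector of survival probabilities in [0, 1].
#' @export
surv_prob <- function(model, t) UseMethod("surv_prob")

#' @export
surv_prob.weibull_model <- function(model, t) {
  pweibull(t, shape = model$shape, scale = model$scale, lower.tail = FALSE)
}

#' @export
surv_prob.survival_curve <- function(model, t) step_surv(model, t)

#' @export
surv_prob.averaged_survival <- function(model, t) {
  (surv_prob(model$model_a, t) + surv_prob(model$model_b, t)) / 2
}

#' Fit a Weibull by log-log linear regression
#'
#' The classical Weibull linearization: for S(t) = exp(-(t/scale)^shape),
#' ln(-ln S(t)) = shape * ln t - shape * ln scale, so ordinary least squares
#' of y = ln(-ln s) on x = ln t gives shape as the slope and
#' scale = exp(-intercept/slope). Points with s = 1 or t = 0 are excluded
#' (the transform is undefined there).
#'
#' @param curve a [survival_curve].
#' @return A [weibull_model()].
#' @examples
#' cv <- survival_curve("exp", 1:10, exp(-(1:10)), n = 100)
#' fit_regression(cv)  # shape 1, scale 1
#' @export
fit_regression <- function(curve) {
  validate_survival_curve(curve)
  use <- curve$time > 0 & curve$surv < 1 & curve$surv > 0
  if (sum(use) < 2L) {
    stop("fit_regression needs >= 2 points with t > 0 and 0 < s < 1 (curve '",
         attr(curve, "label"), "')", call. = FALSE)
  }
  x <- log(curve$time[use])
  y <- log(-log(curve$surv[use]))
  co <- coef(lm(y ~ x))
  slope <- unname(co[2L]); intercept <- unname(co[1L])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-Weibull-compatible curve '", attr(curve, "label"),
         "': log-log regression slope <= 0", call. = FALSE)
  }
  weibull_model(shape = slope, scale = exp(-intercept / slope))
}

# sum of squared differences on the survival scale
weibull_sse <- function(curve, shape, scale) {
  sum((curve$surv - pweibull(curve$time, shape, scale, lower.tail = FALSE))^2)
}

#' Fit a Weibull by least squares on the survival scale
#'
#' Minimizes sum_i (s_i - S(t_i; shape, scale))^2 over the digitized points
#' (all points, including t = 0, enter the objective; they contribute zero
#' residual there). The optimizer is Nelder-Mead restarted from a
#' deterministic set of starting values — the log-log regression fit when it
#' exists, plus a fixed lattice — so results are reproducible without a seed.
#'
#' @param curve a [survival_curve].
#' @param shape_bounds,scale_bounds admissible parameter ranges; the best
#'   start inside the bounds is refined with L-BFGS-B.
#' @return A [weibull_model()] with attribute `sse`, the objective at the
#'   optimum.
#' @export
fit_least_squares <- function(curve,
                              shape_bounds = c(0.05, 20),
                              scale_bounds = c(0.1, 600)) {
  validate_survival_curve(curve)
  if (nrow(curve) < 2L) {
    stop("fit_least_squares needs >= 2 points (curve '",
         attr(curve, "label"), "')", call. = FALSE)
  }
  starts <- list(c(0.5, 3), c(1, 6), c(1.5, 12), c(2, 24), c(3, 48))
  reg <- tryCatch(fit_regression(curve), error = function(e) NULL)
  if (!is.null(reg)) starts <- c(list(c(reg$shape, reg$scale)), starts)

  obj <- function(par) {
    if (par[1] <= 0 || par[2] <= 0) return(Inf)
    weibull_sse(curve, par[1], par[2])
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B",
            lower = c(shape_bounds[1], scale_bounds[1]),
            upper = c(shape_bounds[2], scale_bounds[2]),
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    # polish with Nelder-Mead; L-BFGS-B can stall on the flat shoulder
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("least-squares fit failed to converge from all starts (curve '",
         attr(curve, "label"), "'); check the input points", call. = FALSE)
  }
  out <- weibull_model(best$par[1], best$par[2])
  attr(out, "sse") <- best$value
  out
}

#' Average two extrapolation models pointwise
#'
#' The base-case extrapolation is the mean of the two fitting methods, taken
#' as the pointwise average of survival probabilities:
#' S(t) = (S_a(t) + S_b(t)) / 2. The average is always bounded by the two
#' component curves. (Averaging the Weibull parameters instead would not
#' give the mean survival curve, the model being nonlinear in them.)
#'
#' @param a,b [weibull_model()] objects.
#' @return An object of class `averaged_survival` usable with [surv_prob()].
#' @export
average_models <- function(a, b) {
  stopifnot(inherits(a, "weibull_model"), inherits(b, "weibull_model"))
  structure(list(model_a = a, model_b = b), class = "averaged_survival")
}

#' @export
print.averaged_survival <- function(x, ...) {
  cat("<averaged_survival> pointwise mean of:\n  ")
  print(x$model_a)
  cat("  ")
  print(x$model_b)
  invisible(x)
}

#' Fit one branch by both methods
#'
#' Pools a branch's trial curves, fits by log-log regression and by least
#' squares, and returns the model selected by `method`.
#'
#' @param curves list of [survival_curve] for one model branch.
#' @param method `"mean"` (pointwise average of the two fits; the base
#'   case), `"regression"` or `"least_squares"`.
#' @return The fitted model, with attributes `pooled` (the pooled curve),
#'   `fit_regression` and `fit_least_squares`.
#' @export
fit_branch <- function(curves, method = c("mean", "regression", "least_squares")) {
  method <- match.arg(method)
  pooled <- pool_curves(curves)
  fr <- fit_regression(pooled)
  fl <- fit_least_squares(pooled)
  out <- switch(method,
    mean = average_models(fr, fl),
    regression = fr,
    least_squares = fl
  )
  attr(out, "pooled") <- pooled
  attr(out, "fit_regression") <- fr
  attr(out, "fit_least_squares") <- fl
  out
}

#' Tabulate fitted parameters for a set of branches
#'
#' @param fits named list of [fit_branch()] results (names are branch ids).
#' @return data frame with columns branch, method, shape, scale, sse.
#' @export
fit_report <- function(fits) {
  rows <- lapply(names(fits), function(br) {
    fr <- attr(fits[[br]], "fit_regression")
    fl <- attr(fits[[br]], "fit_least_squares")
    pooled <- attr(fits[[br]], "pooled")
    data.frame(
      branch = br,
      method = c("regression", "least_squares"),
      shape = c(fr$shape, fl$shape),
      scale = c(fr$scale, fl$scale),
      sse = c(weibull_sse(pooled, fr$shape, fr$scale), attr(fl, "sse"))
    )
  })
  do.call(rbind, rows)
}
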