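#' Construct a digitized survival curve
#'
#' A `survival_curve` holds ordered (time, survival) points read off a
#' published Kaplan-Meier figure (or produced by [simulate_km()]) together
#' with the trial sample size used as the pooling weight. Times are in
#' months. A point (0, 1) is prepended when absent so every curve starts at
#' full survival.
#'
#' @param label character identifier of the trial arm / model branch.
#' @param time numeric vector of times in months, strictly increasing, >= 0.
#' @param surv numeric vector of survival probabilities, non-increasing,
#'   in (0, 1].
#' @param n single positive integer, the trial sample size.
#' @return An object of class `survival_curve`: a data frame with columns
#'   `time` and `surv`, attributes `label` and `n`.
#' @examples
#' sc <- survival_curve("arm A", time = c(2, 4, 6), surv = c(0.9, 0.7, 0.5), n = 120)
#' sc
#' @export
survival_curve <- function(label, time, surv, n) {
  stopifnot(is.character(label), length(label) == 1L)
  if (length(time) != length(surv)) {
    stop("`time` and `surv` must have equal length", call. = FALSE)
  }
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer (curve '", label, "')", call. = FALSE)
  }
  ord <- order(time)
  time <- as.numeric(time[ord])
  surv <- as.numeric(surv[ord])
  if (!(length(time) > 0 && time[1] == 0)) {
    time <- c(0, time)
    surv <- c(1, surv)
  }
  out <- structure(
    data.frame(time = time, surv = surv),
    label = label, n = as.integer(n),
    class = c("survival_curve", "data.frame")
  )
  validate_survival_curve(out)
  out
}

validate_survival_curve <- function(x) {
  label <- attr(x, "label")
  if (any(is.na(x$time)) || any(is.na(x$surv))) {
    stop("curve '", label, "': missing values", call. = FALSE)
  }
  if (any(x$time < 0)) stop("curve '", label, "': negative time", call. = FALSE)
  if (any(diff(x$time) <= 0)) {
    stop("curve '", label, "': times must be strictly increasing", call. = FALSE)
  }
  if (any(diff(x$surv) > 1e-12)) {
    stop("curve '", label, "': survival must be non-increasing", call. = FALSE)
  }
  if (any(x$surv <= 0) || any(x$surv > 1)) {
    stop("curve '", label, "': survival must lie in (0, 1]", call. = FALSE)
  }
  if (x$surv[1] != 1) {
    stop("curve '", label, "': first point must have survival 1", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "<survival_curve> '%s' (n = %d, %d points, t in [0, %g] months)\n",
    attr(x, "label"), attr(x, "n"), nrow(x), max(x$time)
  ))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Evaluate a curve by right-continuous step interpolation
#'
#' Kaplan-Meier estimates are right-continuous step functions: between
#' digitized points survival stays at the last observed value. Evaluation
#' beyond the last point returns the last value (extrapolation is the job of
#' the parametric fits).
#'
#' @param curve a [survival_curve].
#' @param t numeric vector of times (months).
#' @return numeric vector of survival probabilities.
#' @export
step_surv <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  idx[idx < 1L] <- 1L
  curve$surv[idx]
}

#' Pool survival curves by trial sample size
#'
#' When several trials inform the same model branch, their curves are
#' combined as a sample-size-weighted average: the pooled survival at time t
#' is sum(n_i * S_i(t)) / sum(n_i), evaluated on the union of the input time
#' grids with step-function interpolation of each input. The pooled sample
#' size is the total.
#'
#' @param curves a list of [survival_curve] objects (length >= 1).
#' @param label label for the pooled curve; defaults to the labels joined
#'   with " + ".
#' @return A [survival_curve] with `n` equal to the summed sample sizes.
#' @examples
#' a <- survival_curve("a", c(6), c(0.8), n = 100)
#' b <- survival_curve("b", c(6), c(0.4), n = 300)
#' pool_curves(list(a, b))$surv  # 1.0, then (100*0.8 + 300*0.4)/400 = 0.5
#' @export
pool_curves <- function(curves, label = NULL) {
  if (length(curves) == 0) stop("no curves", call. = FALSE)
  lapply(curves, validate_survival_curve)
  if (length(curves) == 1L) return(curves[[1L]])
  grid <- sort(unique(unlist(lapply(curves, function(cv) cv$time))))
  w <- vapply(curves, attr, integer(1), "n")
  smat <- vapply(curves, step_surv, numeric(length(grid)), t = grid)
  pooled <- as.numeric(smat %*% w) / sum(w)
  # weighted mean of values each in (0,1]; guard rounding at the boundary
  pooled <- pmin(pooled, 1)
  if (is.null(label)) {
    label <- paste(vapply(curves, attr, character(1), "label"), collapse = " + ")
  }
  survival_curve(label, grid, pooled, n = sum(w))
}

#' Read / write digitized curves as CSV
#'
#' The on-disk format is one file per trial arm with header
#' `time_months,survival,n_at_risk_total`; the sample size is repeated on
#' every row. [read_curve_manifest()] reads a YAML manifest mapping model
#' branches to lists of such files and returns the curves grouped by branch.
#'
#' @param path file path.
#' @param label curve label; defaults to the file name without extension.
#' @return `read_survival_curve()` returns a [survival_curve];
#'   `write_survival_curve()` returns `path` invisibly.
#' @export
read_survival_curve <- function(path, label = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_months", "survival", "n_at_risk_total")
  if (!all(need %in% names(df))) {
    stop("curve file '", path, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  n <- unique(df$n_at_risk_total)
  if (length(n) != 1L) {
    stop("curve file '", path, "' has inconsistent n_at_risk_total", call. = FALSE)
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  survival_curve(label, df$time_months, df$survival, n = n)
}

#' @param curve a [survival_curve].
#' @rdname read_survival_curve
#' @export
write_survival_curve <- function(curve, path) {
  validate_survival_curve(curve)
  df <- data.frame(
    time_months = curve$time,
    survival = curve$surv,
    n_at_risk_total = attr(curve, "n")
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param manifest_path path to a YAML manifest with one entry per branch,
#'   each a list of curve CSV paths (relative paths resolved against the
#'   manifest's directory).
#' @rdname read_survival_curve
#' @export
read_curve_manifest <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  lapply(man, function(files) {
    lapply(files, function(f) {
      p <- if (file.exists(f)) f else file.path(base, f)
      read_survival_curve(p)
    })
  })
}

#' Resample a curve onto a monthly grid
#'
#' Emulates what figure digitization yields: survival read off at whole
#' months, by step interpolation, up to the curve's last observed time.
#'
#' @param curve a [survival_curve].
#' @param by grid step in months.
#' @return A [survival_curve] on the grid `seq(0, max(time), by)`.
#' @export
digitize_monthly <- function(curve, by = 1) {
  grid <- seq(0, max(curve$time), by = by)
  survival_curve(attr(curve, "label"), grid, step_surv(curve, grid),
                 n = attr(curve, "n"))
}
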