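#' Per-cycle transition probabilities from a survival function
#'
#' Converts a survival function into the time-varying conditional event
#' probabilities a monthly-cycle Markov model consumes:
#' p_t = 1 - S(t+1)/S(t) for cycles t = 0..horizon-1, so that the product
#' of (1 - p_u) over u < t reconstructs S(t) exactly at every cycle
#' boundary. If the survival function hits zero before the horizon the
#' remaining probabilities are set to 1 (the state becomes absorbing) and a
#' message is emitted.
#'
#' @param model any object with a [surv_prob()] method.
#' @param horizon number of cycles (months), >= 1.
#' @return An object of class `transition_schedule`: numeric vector `probs`
#'   of length `horizon` plus the `horizon`.
#' @examples
#' m <- weibull_model(1, 10)  # exponential, rate 0.1
#' sched <- to_transition_schedule(m, 60)
#' sched$probs[1]  # 1 - exp(-0.1)
#' @export
to_transition_schedule <- function(model, horizon) {
  stopifnot(length(horizon) == 1L, horizon >= 1, horizon == round(horizon))
  s <- surv_prob(model, 0:horizon)
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("survival function returned values outside [0, 1]", call. = FALSE)
  }
  p <- numeric(horizon)
  zero <- which(s == 0)
  last <- if (length(zero)) zero[1L] - 1L else horizon + 1L
  for (t in seq_len(horizon)) {
    if (s[t] == 0) {
      p[t] <- 1  # survival exhausted: absorbing from here on
    } else {
      p[t] <- 1 - s[t + 1L] / s[t]
    }
  }
  p <- pmin(pmax(p, 0), 1)
  if (length(zero) && zero[1L] <= horizon) {
    message("survival reached 0 at cycle ", zero[1L] - 1L,
            "; remaining transition probabilities set to 1")
  }
  structure(list(probs = p, horizon = as.integer(horizon)),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat(sprintf("<transition_schedule> %d cycles, p in [%.4g, %.4g]\n",
              x$horizon, min(x$probs), max(x$probs)))
  invisible(x)
}

#' Survival implied by a transition schedule
#'
#' The round-trip companion of [to_transition_schedule()]: cumulative
#' products of (1 - p_t), giving survival at cycle boundaries 0..horizon.
#'
#' @param schedule a `transition_schedule`.
#' @return numeric vector of length horizon + 1.
#' @export
schedule_survival <- function(schedule) {
  c(1, cumprod(1 - schedule$probs))
}

#' Export a schedule as CSV (columns cycle, p_event)
#'
#' @param schedule a `transition_schedule`.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(
    data.frame(cycle = seq_len(schedule$horizon) - 1L, p_event = schedule$probs),
    path, row.names = FALSE
  )
  invisible(path)
}
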