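#' Define a treatment line
#'
#' A treatment line is one station on a pathway: a regimen with its
#' progression (PFS) and death (OS) schedules, per-cycle costs split into an
#' administration and a post-administration phase, a health-state utility,
#' and an adverse-event disutility burden. Best supportive care (BSC) is the
#' terminal line: it has no PFS schedule (no further progression) and its OS
#' schedule is the BSC survival curve.
#'
#' Chemotherapy doublets are administered for a fixed number of cycles
#' (`admin_cycles = 4` here) and the cheaper non-administration cost applies
#' from then until progression. Oral targeted therapy is taken until
#' progression, so `admin_cycles = Inf` and the administration cost applies
#' to every occupied cycle; the same convention prices BSC.
#'
#' @param label regimen label.
#' @param pfs,os [to_transition_schedule()] objects indexed by cycles since
#'   line entry; `pfs = NULL` marks the terminal BSC line.
#' @param cost_admin,cost_nonadmin cost (USD) per cycle during and after the
#'   administration phase.
#' @param admin_cycles number of cycles on the administration cost
#'   (may be `Inf`).
#' @param utility health-state utility (QALY weight per year) while in this
#'   line.
#' @param is_oral logical; oral regimens receive `oral_adjustment` on top of
#'   the utility (the utility source valued intravenous regimens).
#' @param ae_disutility total adverse-event disutility (sum over events of
#'   incidence x per-event disutility), subtracted from the utility in the
#'   line-entry cycle only — or over the whole administration phase when
#'   `ae_whole_period` is `TRUE`.
#' @param ae_whole_period apply `ae_disutility` for every administration
#'   cycle instead of the entry cycle only (a scenario switch).
#' @param oral_adjustment utility increment for oral administration.
#' @param iv_disutility utility decrement applied while a non-oral line is
#'   in its administration phase, when injections actually occur (0 in the
#'   base case; a scenario switch).
#' @return An object of class `treatment_line`.
#' @export
treatment_line <- function(label, pfs, os,
                           cost_admin, cost_nonadmin = cost_admin,
                           admin_cycles = Inf,
                           utility,
                           is_oral = FALSE,
                           ae_disutility = 0,
                           ae_whole_period = FALSE,
                           oral_adjustment = 0.02,
                           iv_disutility = 0) {
  stopifnot(is.null(pfs) || inherits(pfs, "transition_schedule"),
            inherits(os, "transition_schedule"))
  if (cost_admin < 0 || cost_nonadmin < 0) stop("costs must be >= 0", call. = FALSE)
  if (utility < 0 || utility > 1) stop("`utility` must be in [0, 1]", call. = FALSE)
  if (admin_cycles < 0) stop("`admin_cycles` must be >= 0", call. = FALSE)
  if (ae_disutility < 0) stop("`ae_disutility` is a magnitude, >= 0", call. = FALSE)
  structure(
    list(label = label, pfs = pfs, os = os,
         cost_admin = cost_admin, cost_nonadmin = cost_nonadmin,
         admin_cycles = admin_cycles, utility = utility, is_oral = is_oral,
         ae_disutility = ae_disutility, ae_whole_period = ae_whole_period,
         oral_adjustment = oral_adjustment, iv_disutility = iv_disutility),
    class = "treatment_line"
  )
}

#' Define a strategy as weighted treatment pathways
#'
#' A strategy mixes one or more arms, each a cohort fraction following an
#' ordered list of [treatment_line()]s that must end in a BSC line (no PFS
#' schedule). For a test-and-treat strategy the weights come from
#' [branch_proportions()]; a no-testing strategy has a single arm of
#' weight 1 and `test_cost = 0`.
#'
#' @param name strategy name.
#' @param arms list of `list(weight = , lines = list(...))`; weights must
#'   sum to 1.
#' @param test_cost one-off diagnostic cost (USD) charged to the whole
#'   cohort at cycle 0.
#' @return An object of class `strategy_definition`.
#' @export
strategy_definition <- function(name, arms, test_cost = 0) {
  w <- vapply(arms, function(a) a$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop("arm weights must sum to 1", call. = FALSE)
  if (test_cost < 0) stop("`test_cost` must be >= 0", call. = FALSE)
  for (a in arms) {
    last <- a$lines[[length(a$lines)]]
    if (!is.null(last$pfs)) {
      stop("every pathway must end in a BSC line (no PFS schedule)",
           call. = FALSE)
    }
  }
  structure(list(name = name, arms = arms, test_cost = test_cost),
            class = "strategy_definition")
}

#' Cycle settings for the cohort model
#'
#' @param horizon number of monthly cycles (60 = five years).
#' @param annual_discount_rate annual discount rate applied to both costs
#'   and QALYs (0.03 in the base case).
#' @param cycle_length_months cycle length; the model is built around
#'   1-month cycles.
#' @param half_cycle_correction average start- and end-of-cycle occupancy
#'   when accruing (off by default).
#' @return An object of class `cycle_config`.
#' @export
cycle_config <- function(horizon = 60, annual_discount_rate = 0.03,
                         cycle_length_months = 1,
                         half_cycle_correction = FALSE) {
  stopifnot(horizon >= 1, horizon == round(horizon),
            annual_discount_rate >= 0, cycle_length_months > 0)
  structure(list(horizon = as.integer(horizon),
                 annual_discount_rate = annual_discount_rate,
                 cycle_length_months = cycle_length_months,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "cycle_config")
}

discount_factors <- function(config) {
  t <- seq_len(config$horizon) - 1L
  (1 + config$annual_discount_rate)^(-(t * config$cycle_length_months) / 12)
}

# One arm of a strategy: clock-expanded occupancy matrices.
# occ[[l]][t + 1, tau + 1] = fraction in line l at cycle t with clock tau
# (tau = cycles since line entry). Transitions happen at cycle boundaries:
# row t + 1 is the state occupied during cycle t + 1; fractions dying at a
# boundary accrue nothing from that cycle on. Death takes priority within a
# cycle: the progression probability is the PFS event probability minus the
# death probability, floored at zero (clamps are counted).
run_arm <- function(lines, config) {
  H <- config$horizon
  nl <- length(lines)
  for (ln in lines) {
    if (!is.null(ln$pfs) && ln$pfs$horizon < H) {
      stop("PFS schedule of line '", ln$label,
           "' is shorter than the horizon", call. = FALSE)
    }
    if (ln$os$horizon < H) {
      stop("OS schedule of line '", ln$label,
           "' is shorter than the horizon", call. = FALSE)
    }
  }
  occ <- lapply(seq_len(nl), function(i) matrix(0, H + 1L, H + 1L))
  dead <- numeric(H + 1L)
  occ[[1L]][1L, 1L] <- 1
  clamped <- 0L
  for (t in seq_len(H)) {           # transition into row t + 1
    for (l in seq_len(nl)) {
      m <- occ[[l]][t, seq_len(t)]  # clocks 0..t-1 are reachable at cycle t-1
      if (all(m == 0)) next
      pd <- lines[[l]]$os$probs[seq_len(t)]
      if (is.null(lines[[l]]$pfs)) {
        pp <- numeric(t)
      } else {
        raw <- lines[[l]]$pfs$probs[seq_len(t)] - pd
        clamped <- clamped + sum(raw < 0 & m > 0)
        pp <- pmax(0, raw)
      }
      occ[[l]][t + 1L, 1L + seq_len(t)] <-
        occ[[l]][t + 1L, 1L + seq_len(t)] + m * (1 - pd - pp)
      dead[t + 1L] <- dead[t + 1L] + sum(m * pd)
      if (l < nl) {
        occ[[l + 1L]][t + 1L, 1L] <- occ[[l + 1L]][t + 1L, 1L] + sum(m * pp)
      }
    }
    dead[t + 1L] <- dead[t + 1L] + dead[t]
  }
  structure(list(lines = lines, occ = occ, dead = dead,
                 clamped = clamped, config = config),
            class = "arm_trace")
}

#' Run the cohort model for a strategy
#'
#' Pushes a cohort of size 1 through each arm's treatment pathway over the
#' configured horizon. States are clock-expanded: a fraction occupying line
#' L with clock tau faces that line's OS death probability at index tau and,
#' unless already in BSC, progresses with the PFS event probability minus
#' the death probability (floored at 0). Progression moves the fraction to
#' the next line with its clock reset to 0 (semi-Markov); progression from
#' the last treatment line enters BSC; death is absorbing.
#'
#' @param strategy a [strategy_definition()].
#' @param config a [cycle_config()].
#' @return An object of class `cohort_trace` holding one arm trace per
#'   strategy arm. `as.data.frame()` gives the per-cycle occupancy by line
#'   (clocks summed), weighted across arms.
#' @export
run_cohort <- function(strategy, config) {
  stopifnot(inherits(strategy, "strategy_definition"),
            inherits(config, "cycle_config"))
  arms <- lapply(strategy$arms, function(a) run_arm(a$lines, config))
  clamped <- sum(vapply(arms, function(a) a$clamped, numeric(1)))
  if (clamped > 0) {
    message(clamped, " progression probabilities fell below the death ",
            "probability and were clamped to 0")
  }
  structure(list(strategy = strategy, arms = arms, config = config),
            class = "cohort_trace")
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  H <- x$config$horizon
  w <- vapply(x$strategy$arms, function(a) a$weight, numeric(1))
  labels <- unique(unlist(lapply(x$arms, function(a)
    vapply(a$lines, function(ln) ln$label, character(1)))))
  out <- matrix(0, H + 1L, length(labels) + 1L,
                dimnames = list(NULL, c(labels, "dead")))
  for (i in seq_along(x$arms)) {
    a <- x$arms[[i]]
    for (l in seq_along(a$lines)) {
      lab <- a$lines[[l]]$label
      out[, lab] <- out[, lab] + w[i] * rowSums(a$occ[[l]])
    }
    out[, "dead"] <- out[, "dead"] + w[i] * a$dead
  }
  data.frame(cycle = 0:H, out, check.names = FALSE)
}

#' @export
print.cohort_trace <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<cohort_trace> strategy '%s', %d arms, %d cycles\n",
              x$strategy$name, length(x$arms), x$config$horizon))
  print(df[c(1, seq(12, nrow(df) - 1, by = 12), nrow(df)), ], row.names = FALSE)
  invisible(x)
}

# accrual weights per (cycle, clock) for one arm trace; f(line, tau_vector)
# returns the per-cycle value for each clock
accrue_arm <- function(arm, per_cycle_value) {
  H <- arm$config$horizon
  disc <- discount_factors(arm$config)
  hcc <- arm$config$half_cycle_correction
  total <- 0
  for (l in seq_along(arm$lines)) {
    vals <- per_cycle_value(arm$lines[[l]], 0:H)   # value by clock 0..H
    m <- arm$occ[[l]]
    cyc <- as.numeric(m[seq_len(H), ] %*% vals)    # rows 0..H-1
    if (hcc) cyc <- (cyc + as.numeric(m[2:(H + 1L), ] %*% vals)) / 2
    total <- total + sum(disc * cyc)
  }
  total
}

#' Accumulate discounted costs over a cohort trace
#'
#' Each cycle, every occupied line accrues its administration-phase cost
#' while the line clock is below `admin_cycles` and its non-administration
#' cost afterwards; the diagnostic test cost is charged once to the whole
#' cohort at cycle 0. Cycle t is discounted by (1 + r)^(-t/12). Fractions
#' dead at a cycle boundary accrue nothing from that cycle on.
#'
#' @param trace a [run_cohort()] result.
#' @param strategy the same [strategy_definition()] the trace was run under.
#' @param config the same [cycle_config()].
#' @return Discounted cost (USD) per patient.
#' @export
accumulate_costs <- function(trace, strategy = trace$strategy,
                             config = trace$config) {
  stopifnot(inherits(trace, "cohort_trace"))
  w <- vapply(strategy$arms, function(a) a$weight, numeric(1))
  per_arm <- vapply(trace$arms, accrue_arm, numeric(1),
                    per_cycle_value = function(line, tau) {
                      ifelse(tau < line$admin_cycles,
                             line$cost_admin, line$cost_nonadmin)
                    })
  sum(w * per_arm) + strategy$test_cost
}

#' Accumulate discounted QALYs over a cohort trace
#'
#' The per-cycle increment is occupancy x effective utility / 12, where the
#' effective utility is the line utility plus the oral adjustment for oral
#' regimens, minus any intravenous-administration disutility, minus the
#' adverse-event disutility in the line-entry cycle (or all administration
#' cycles when the line's `ae_whole_period` switch is on). Discounting as
#' for costs.
#'
#' @inheritParams accumulate_costs
#' @return Discounted QALYs per patient.
#' @export
accumulate_qalys <- function(trace, strategy = trace$strategy,
                             config = trace$config) {
  stopifnot(inherits(trace, "cohort_trace"))
  w <- vapply(strategy$arms, function(a) a$weight, numeric(1))
  per_arm <- vapply(trace$arms, accrue_arm, numeric(1),
                    per_cycle_value = function(line, tau) {
                      u <- line$utility +
                        (if (line$is_oral) line$oral_adjustment else 0)
                      u <- u - (tau < line$admin_cycles) * line$iv_disutility
                      if (any(u < -0.2 | u > 1)) {
                        stop("effective utility of line '", line$label,
                             "' outside [-0.2, 1]; check the utility ",
                             "configuration", call. = FALSE)
                      }
                      ae_on <- if (line$ae_whole_period) {
                        tau < line$admin_cycles
                      } else {
                        tau == 0
                      }
                      (u - ae_on * line$ae_disutility) / 12
                    })
  sum(w * per_arm)
}

#' Evaluate one strategy end to end
#'
#' Runs the cohort and returns discounted cost and QALYs as a `ce_result`.
#'
#' @param strategy a [strategy_definition()].
#' @param config a [cycle_config()].
#' @return A `ce_result`: list with `strategy`, `cost` (USD) and `effect`
#'   (QALYs), plus the trace as attribute `trace`.
#' @export
evaluate_strategy <- function(strategy, config) {
  trace <- run_cohort(strategy, config)
  out <- ce_result(strategy$name,
                   cost = accumulate_costs(trace, strategy, config),
                   effect = accumulate_qalys(trace, strategy, config))
  attr(out, "trace") <- trace
  out
}

#' Cost-effectiveness result for one strategy
#'
#' @param strategy strategy name.
#' @param cost discounted cost (USD), >= 0.
#' @param effect discounted effect (QALYs), >= 0.
#' @return An object of class `ce_result`.
#' @export
ce_result <- function(strategy, cost, effect) {
  if (cost < 0 || effect < 0) stop("cost and effect must be >= 0", call. = FALSE)
  structure(list(strategy = strategy, cost = cost, effect = effect),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s: cost $%s, effect %.5f QALY\n",
              x$strategy, format(round(x$cost), big.mark = ","), x$effect))
  invisible(x)
}
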