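test_that("with no events the cohort never leaves the first line", {
  lines <- list(
    toy_line("l1", pfs = 0, p_death = rep(0, 60)),
    toy_line("bsc", p_death = rep(0, 60))
  )
  trace <- run_cohort(toy_strategy(lines), cycle_config(horizon = 60))
  df <- as.data.frame(trace)
  expect_equal(df$l1, rep(1, 61))
  expect_equal(df$dead, rep(0, 61))
})

test_that("certain death at cycle 0 absorbs the whole cohort", {
  lines <- list(
    toy_line("l1", pfs = 0, p_death = c(1, rep(0, 9))),
    toy_line("bsc", p_death = rep(0, 10))
  )
  df <- as.data.frame(run_cohort(toy_strategy(lines), cycle_config(horizon = 10)))
  expect_equal(df$dead[2], 1)
  expect_equal(df$dead[11], 1)
})

test_that("one-step update matches the hand-computed two-cycle toy", {
  # p_pfs = 0.5, p_death = 0.2 on the chemo line; BSC death 0.1
  lines <- list(
    toy_line("chemo", pfs = 0.5, p_death = rep(0.2, 2)),
    toy_line("bsc", p_death = rep(0.1, 2))
  )
  trace <- run_cohort(toy_strategy(lines), cycle_config(horizon = 2))
  arm <- trace$arms[[1]]
  # cycle 1: stay = 1 - 0.2 - (0.5 - 0.2) = 0.5; dead 0.2; BSC clock 0 = 0.3
  expect_equal(arm$occ[[1]][2, 2], 0.5)
  expect_equal(arm$dead[2], 0.2)
  expect_equal(arm$occ[[2]][2, 1], 0.3)
})

test_that("occupancy is conserved and death is absorbing on a full run", {
  run <- evaluate_cea(default_config(), test_curves())
  for (nm in c("testing", "no_testing")) {
    trace <- attr(run$ce[[nm]], "trace")
    for (arm in trace$arms) {
      alive <- Reduce(`+`, lapply(arm$occ, rowSums))
      expect_equal(alive + arm$dead, rep(1, 61), tolerance = 1e-10)
      expect_true(all(diff(arm$dead) >= -1e-15))
    }
  }
})

test_that("with progression disabled the alive fraction follows the OS curve", {
  m <- weibull_model(1.6, 14)
  os <- to_transition_schedule(m, 60)
  lines <- list(treatment_line("only", pfs = NULL, os = os,
                               cost_admin = 0, utility = 0.5))
  trace <- run_cohort(toy_strategy(lines), cycle_config(horizon = 60))
  alive <- rowSums(trace$arms[[1]]$occ[[1]])
  expect_equal(alive, surv_prob(m, 0:60), tolerance = 1e-10)
})

test_that("clocks reset on line entry (semi-Markov)", {
  # deterministic progression at clock 0 of line 1; line 2 kills only at
  # its clock 1, i.e. model cycle 2
  lines <- list(
    toy_line("l1", pfs = 1, p_death = rep(0, 5)),
    treatment_line("l2", pfs = NULL, os = toy_schedule(c(0, 1, 0, 0, 0)),
                   cost_admin = 0, utility = 0.5)
  )
  trace <- run_cohort(toy_strategy(lines), cycle_config(horizon = 5))
  arm <- trace$arms[[1]]
  expect_equal(arm$occ[[2]][2, 1], 1)  # enters l2 at cycle 1 with clock 0
  expect_equal(arm$dead[3], 0)         # index 0 (p = 0) governs cycle 1
  expect_equal(arm$dead[4], 1)         # index 1 (p = 1) during cycle 2
})

test_that("costs follow the administration phase and the test is charged once", {
  conf0 <- cycle_config(horizon = 60, annual_discount_rate = 0)
  # erlotinib-style line occupied for the whole horizon
  ert <- list(toy_line("ert", p_death = rep(0, 60),
                       cost_admin = 2113, admin_cycles = Inf, utility = 0.6))
  trace <- run_cohort(toy_strategy(ert), conf0)
  expect_equal(accumulate_costs(trace), 60 * 2113)

  # only a test cost, with nonzero discounting: charged undiscounted at t=0
  conf_r <- cycle_config(horizon = 60, annual_discount_rate = 0.05)
  free <- list(toy_line("idle", p_death = rep(0, 60),
                        cost_admin = 0, utility = 0.6))
  trace_free <- run_cohort(toy_strategy(free, test_cost = 104), conf_r)
  expect_equal(accumulate_costs(trace_free), 104)

  # chemotherapy: 4 administration cycles then maintenance pricing
  conf10 <- cycle_config(horizon = 10, annual_discount_rate = 0)
  chemo <- list(toy_line("cpem", p_death = rep(0, 10),
                         cost_admin = 4157, cost_nonadmin = 503,
                         admin_cycles = 4, utility = 0.6))
  trace_c <- run_cohort(toy_strategy(chemo), conf10)
  expect_equal(accumulate_costs(trace_c), 4 * 4157 + 6 * 503)
})

test_that("QALY accrual applies utilities, oral adjustment and AE disutility", {
  conf12 <- cycle_config(horizon = 12, annual_discount_rate = 0)
  stay <- function(...) list(toy_line(..., p_death = rep(0, 12)))

  # one year at weight 0.6
  tr <- run_cohort(toy_strategy(stay("a", utility = 0.6)), conf12)
  expect_equal(accumulate_qalys(tr), 0.6)

  # oral adjustment: 0.6532 + 0.02 per cycle
  tr_oral <- run_cohort(toy_strategy(stay("o", utility = 0.6532,
                                          is_oral = TRUE)), conf12)
  expect_equal(accumulate_qalys(tr_oral), 0.6732)

  # entry-cycle AE disutility shifts the total by exactly 0.09/12
  tr_ae <- run_cohort(toy_strategy(stay("ae", utility = 0.6,
                                        ae_disutility = 0.09)), conf12)
  expect_equal(accumulate_qalys(tr) - accumulate_qalys(tr_ae), 0.09 / 12)

  # whole-period AE on a 4-cycle administration phase: 4 x 0.09/12
  tr_ae4 <- run_cohort(toy_strategy(stay("ae4", utility = 0.6,
                                         ae_disutility = 0.09,
                                         admin_cycles = 4,
                                         ae_whole_period = TRUE)), conf12)
  expect_equal(accumulate_qalys(tr) - accumulate_qalys(tr_ae4), 4 * 0.09 / 12)

  # nonsense utility configuration is caught
  bad <- toy_strategy(list(toy_line("bad", p_death = rep(0, 12),
                                    utility = 0.99, is_oral = TRUE,
                                    oral_adjustment = 0.2)))
  expect_error(accumulate_qalys(run_cohort(bad, conf12)), "outside")
})

test_that("discounting decreases totals monotonically and r = 0 is the raw sum", {
  lines <- list(toy_line("l", p_death = rep(0, 24),
                         cost_admin = 100, utility = 0.5))
  vals <- vapply(c(0, 0.03, 0.06, 0.12), function(r) {
    conf <- cycle_config(horizon = 24, annual_discount_rate = r)
    tr <- run_cohort(toy_strategy(lines), conf)
    c(accumulate_costs(tr), accumulate_qalys(tr))
  }, numeric(2))
  expect_equal(vals[1, 1], 24 * 100)
  expect_equal(vals[2, 1], 0.5 * 2)
  expect_true(all(diff(vals[1, ]) < 0))
  expect_true(all(diff(vals[2, ]) < 0))
})

test_that("a mixed strategy is the weight-average of its arms", {
  conf <- cycle_config(horizon = 24, annual_discount_rate = 0.03)
  os_a <- to_transition_schedule(weibull_model(1.2, 10), 24)
  os_b <- to_transition_schedule(weibull_model(1.8, 18), 24)
  arm_a <- list(treatment_line("a", pfs = toy_schedule(rep(0.05, 24)), os = os_a,
                               cost_admin = 900, utility = 0.6),
                toy_line("bsc_a", p_death = rep(0.1, 24), cost_admin = 1038,
                         utility = 0.47))
  arm_b <- list(treatment_line("b", pfs = toy_schedule(rep(0.2, 24)), os = os_b,
                               cost_admin = 2000, utility = 0.55),
                toy_line("bsc_b", p_death = rep(0.15, 24), cost_admin = 1038,
                         utility = 0.47))
  mixed <- strategy_definition("mix", list(list(weight = 0.3, lines = arm_a),
                                           list(weight = 0.7, lines = arm_b)))
  only_a <- toy_strategy(arm_a, name = "a")
  only_b <- toy_strategy(arm_b, name = "b")
  ce_mix <- evaluate_strategy(mixed, conf)
  ce_a <- evaluate_strategy(only_a, conf)
  ce_b <- evaluate_strategy(only_b, conf)
  expect_equal(ce_mix$cost, 0.3 * ce_a$cost + 0.7 * ce_b$cost, tolerance = 1e-12)
  expect_equal(ce_mix$effect, 0.3 * ce_a$effect + 0.7 * ce_b$effect,
               tolerance = 1e-12)
})

test_that("schedules shorter than the horizon are rejected", {
  lines <- list(toy_line("l", p_death = rep(0, 10)))
  expect_error(run_cohort(toy_strategy(lines), cycle_config(horizon = 20)),
               "shorter than the horizon")
})

test_that("pathways must end in a BSC line without a PFS schedule", {
  with_pfs <- list(toy_line("l", pfs = 0.1, p_death = rep(0, 10)))
  expect_error(toy_strategy(with_pfs), "BSC")
})
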