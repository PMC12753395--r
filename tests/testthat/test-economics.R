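test_that("discount factors follow the compound annual convention", {
  expect_equal(monthly_discount_factor(0, 1:120), rep(1, 120))
  expect_equal(monthly_discount_factor(0.05, 12), 1 / 1.05)
  expect_equal(monthly_discount_factor(0.05, 1), 1.05^(-1 / 12))
  expect_equal(monthly_discount_factor(0.05, 120), 1.05^-10)
  expect_error(monthly_discount_factor(1, 1), "\\[0, 1\\)")
  expect_error(monthly_discount_factor(-0.01, 1), "\\[0, 1\\)")
})

test_that("strategy evaluation accrues utilities and costs as documented", {
  # cohort pinned in DFS, zero discount: one healthy year = u_dfs QALYs
  pin <- run_trace(transition_matrix(0, 0, 0), n_cycles = 12)
  p <- strategy_params("pin", 14, 22, u_dfs = 0.792, u_pd = 0.65,
                       initial_cost = 1000, cycle_cost_alive = 0,
                       annual_discount = 0)
  ec <- evaluate_strategy(p, pin)
  expect_equal(ec$total_qalys, 0.792)
  # zero per-cycle cost: total is the initial cost regardless of the trace
  expect_equal(ec$total_cost, 1000)
  tr <- run_trace(build_transition_matrix(14, 22))
  ec2 <- evaluate_strategy(strategy_params("a", 14, 22, 0.792, 0.65,
                                           95994.18, 0, 0.05), tr)
  expect_equal(ec2$total_cost, 95994.18)
  expect_error(evaluate_strategy(p, list()), "markov_trace")
})

test_that("evaluation is exactly linear in per-cycle cost and utilities", {
  tr <- run_trace(build_transition_matrix(14, 22))
  base <- function(cc, u1, u2) {
    evaluate_strategy(
      strategy_params("x", 14, 22, u1, u2, 50000, cc, 0.05), tr)
  }
  e0 <- base(0, 0.792, 0.65)
  e1 <- base(4000, 0.792, 0.65)
  e2 <- base(8000, 0.792, 0.65)
  expect_equal(e2$total_cost - e0$total_cost,
               2 * (e1$total_cost - e0$total_cost))
  # utility linearity: QALYs at (u_dfs, 0) plus (0, u_pd) add up
  eu <- base(0, 0.792, 0)
  ep <- base(0, 0, 0)  # u_pd = u_dfs = 0
  em <- base(0, 0.792, 0.65)
  e_pd_only <- evaluate_strategy(
    new_params <- structure(list(label = "x", median_dfs = 14, median_os = 22,
                                 u_dfs = 0, u_pd = 0.65, initial_cost = 50000,
                                 cycle_cost_alive = 0, annual_discount = 0.05),
                            class = "strategy_params"), tr)
  expect_equal(em$total_qalys, eu$total_qalys + e_pd_only$total_qalys,
               tolerance = 1e-12)
  expect_equal(ep$total_qalys, 0)
})

test_that("discounting reduces totals and longer horizons accrue more", {
  m <- build_transition_matrix(14, 22)
  mk <- function(n, rate) {
    evaluate_strategy(strategy_params("s", 14, 22, 0.792, 0.65, 0, 5000,
                                      rate), run_trace(m, n_cycles = n))
  }
  undisc <- mk(120, 0)
  disc <- mk(120, 0.05)
  expect_lt(disc$total_cost, undisc$total_cost)
  expect_lt(disc$total_qalys, undisc$total_qalys)
  horizons <- c(12, 60, 120, 240)
  qalys <- vapply(horizons, function(n) mk(n, 0.05)$total_qalys, numeric(1))
  costs <- vapply(horizons, function(n) mk(n, 0.05)$total_cost, numeric(1))
  expect_true(all(diff(qalys) > 0))
  expect_true(all(diff(costs) > 0))
})

test_that("ICER decisions follow the WTP rule and dominance cases", {
  ref <- econ_result("ref", 100000, 1.0)
  # more effective and costlier: compare ICER with WTP
  ce <- icer(ref, econ_result("cmp", 120000, 1.5), wtp = 50000)
  expect_equal(ce$icer, 40000)
  expect_identical(ce$decision, "cost-effective")
  ce2 <- icer(ref, econ_result("cmp", 150000, 1.5), wtp = 50000)
  expect_identical(ce2$decision, "not-cost-effective")
  # cheaper and more effective: dominant
  expect_identical(icer(ref, econ_result("c", 90000, 1.2), 50000)$decision,
                   "dominant")
  # costlier and less effective: dominated
  expect_identical(icer(ref, econ_result("c", 110000, 0.8), 50000)$decision,
                   "dominated")
  # identical results: undefined ICER, equivalent
  same <- icer(ref, econ_result("c", 100000, 1.0), 50000)
  expect_true(is.na(same$icer))
  expect_identical(same$decision, "equivalent")
  # both increments negative: savings per QALY forgone, reversed flag
  rev <- icer(ref, econ_result("c", 40000, 0.5), 50000)
  expect_true(rev$reversed)
  expect_equal(rev$icer, 120000)
  expect_identical(rev$decision, "cost-effective")
})

test_that("net monetary benefit is consistent with the ICER", {
  ref <- econ_result("ref", 269164.88, 2.190)
  cmp <- econ_result("cmp", 282340.19, 2.254)
  expect_equal(nmb(ref, 0), -269164.88)
  ce <- icer(ref, cmp, 268074)
  # indifference: the NMB difference vanishes exactly at wtp = ICER
  expect_equal(nmb(cmp, ce$icer) - nmb(ref, ce$icer), 0, tolerance = 1e-6)
  # and flips sign on either side
  expect_gt(nmb(cmp, ce$icer * 1.01) - nmb(ref, ce$icer * 1.01), 0)
  expect_lt(nmb(cmp, ce$icer * 0.99) - nmb(ref, ce$icer * 0.99), 0)
})

test_that("per-cycle cost calibration is an exact linear solve", {
  tr <- run_trace(build_transition_matrix(14, 22))
  expect_equal(calibrate_state_costs(tr, 50000, 50000, 0.05), 0)
  c1 <- calibrate_state_costs(tr, 150000, 50000, 0.05)
  c2 <- calibrate_state_costs(tr, 250000, 50000, 0.05)
  expect_equal(c2, 2 * c1)
  # round trip through evaluate_strategy
  p <- strategy_params("x", 14, 22, 0.792, 0.65, 50000, c1, 0.05)
  expect_equal(evaluate_strategy(p, tr)$total_cost, 150000, tolerance = 1e-8)
  expect_error(calibrate_state_costs(tr, 1000, 50000, 0.05), "at least")
  dead <- run_trace(build_transition_matrix(14, 22), initial = c(0, 0, 1))
  expect_error(calibrate_state_costs(dead, 60000, 50000, 0.05),
               "person-time")
})
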