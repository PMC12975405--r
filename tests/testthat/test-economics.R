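test_that("program cost build-up reproduces the published panel budget", {
  res <- program_cost_per_participant()
  bd <- res$breakdown
  expect_equal(round_half_up(bd[["fringe"]]), 24898)
  expect_equal(round_half_up(bd[["total_personnel"]]), 100347)
  expect_equal(bd[["total_operating"]], 10077)
  expect_equal(round_half_up(bd[["total_direct"]]), 110424)
  expect_equal(round_half_up(bd[["indirect"]], 2), 11042.40)
  # direct + indirect exactly; the published grand total is rounded up by
  # ~$0.60 relative to its own subtotals and is not asserted
  expect_equal(bd[["total"]], 110424 + 11042.40)
  expect_equal(round_half_up(res$per_participant), 1215)
})

test_that("program cost arithmetic holds on constructed inputs", {
  # 10,000 * 1.33 * 1.10 / 100 = 146.30 by hand
  single <- program_cost_inputs(personnel = c(w = 10000),
                                operating = numeric(0),
                                fringe_rate = 0.33, indirect_rate = 0.10,
                                panel_size = 100)
  expect_equal(program_cost_per_participant(single)$per_participant, 146.30)

  zero <- program_cost_inputs(personnel = c(w = 0), operating = c(o = 0))
  expect_equal(program_cost_per_participant(zero)$per_participant, 0)

  expect_error(program_cost_inputs(panel_size = 0),
               class = "markovcea_config_error")
  expect_error(program_cost_inputs(personnel = c(w = -5)),
               class = "markovcea_config_error")
})

healthy_forever_trace <- function(horizon = 20, discount_rate = 0) {
  I5 <- diag(5); dimnames(I5) <- list(model_states(), model_states())
  tm <- validate_matrix(transition_matrix(I5), policy = "error")$matrix
  run_cohort(tm, simulation_settings(horizon = horizon,
                                     discount_rate = discount_rate))
}

test_that("expected costs accumulate maintenance, event and program streams", {
  s <- model_states()
  zero_states <- stats::setNames(rep(0, 5), s)
  zero_events <- matrix(0, 5, 5, dimnames = list(s, s))

  # program cost only: 1215/year * 20 undiscounted years
  sched <- cost_schedule(state_costs = zero_states, event_costs = zero_events,
                         program_cost = 1215, placeholder = FALSE)
  tr <- healthy_forever_trace()
  res <- expected_costs(tr, sched)
  expect_equal(res$discounted, 24300)
  expect_equal(res$undiscounted, 24300)

  # zero schedule entirely
  sched0 <- cost_schedule(state_costs = zero_states, event_costs = zero_events,
                          program_cost = 0, placeholder = FALSE)
  expect_equal(expected_costs(tr, sched0)$discounted, 0)

  # state 100/yr + program 1215/yr over 2 alive cycles
  sc <- zero_states; sc[s != "death"] <- 100
  sched2 <- cost_schedule(state_costs = sc, event_costs = zero_events,
                          program_cost = 1215, placeholder = FALSE)
  tr2 <- healthy_forever_trace(horizon = 2)
  expect_equal(expected_costs(tr2, sched2)$discounted, 2630)

  # discounting shrinks totals; accounting identity holds per cycle
  trd <- healthy_forever_trace(discount_rate = 0.03)
  resd <- expected_costs(trd, sched)
  expect_lt(resd$discounted, resd$undiscounted)
  expect_equal(resd$discounted, sum(rowSums(resd$per_cycle[, -1])),
               tolerance = 1e-9)

  # event costs: deterministic healthy -> death in one cycle
  P <- diag(5); dimnames(P) <- list(s, s)
  P["healthy", ] <- c(0, 0, 0, 0, 1)
  tmd <- validate_matrix(transition_matrix(P), policy = "error")$matrix
  ev <- zero_events; ev["healthy", "death"] <- 5000
  schedd <- cost_schedule(state_costs = zero_states, event_costs = ev,
                          program_cost = 0, placeholder = FALSE)
  trdth <- run_cohort(tmd, simulation_settings(horizon = 3, discount_rate = 0))
  expect_equal(expected_costs(trdth, schedd)$discounted, 5000)

  # missing edge with nonzero flow is named
  ev_na <- zero_events; ev_na["healthy", "death"] <- NA
  sched_na <- cost_schedule(state_costs = zero_states, event_costs = ev_na,
                            program_cost = 0, placeholder = FALSE)
  expect_error(expected_costs(trdth, sched_na), "healthy -> death",
               class = "markovcea_data_error")
})

test_that("placeholder schedules demand explicit confirmation", {
  sched <- cost_schedule()
  expect_true(sched$placeholder)
  tr <- healthy_forever_trace(horizon = 2)
  expect_error(expected_costs(tr, sched), "placeholder",
               class = "markovcea_config_error")
  expect_warning(expected_costs(tr, sched, allow_placeholder = TRUE),
                 "placeholder")
})

test_that("ICERs divide, round half-up, and flag degenerate cases", {
  expect_equal(icer(8344, 1.0)$value, 8344)
  expect_equal(icer(6649, 0.9)$value, 7388)
  expect_equal(icer(0, 0.5)$value, 0)
  expect_equal(icer(100, 0)$flag, "dominated/undefined")
  expect_true(is.na(icer(100, 0)$value))
  expect_equal(icer(100, -0.5)$flag, "dominated/undefined")
  expect_equal(icer(-100, -0.5)$flag, "cost-saving")
  expect_equal(icer(-100, 0.5)$flag, "cost-saving")
  expect_equal(icer(-100, 0.5)$value, -200)

  # scale covariance on the unrounded value
  base <- icer(1234.5, 0.37)$value_exact
  expect_equal(icer(3 * 1234.5, 0.37)$value_exact, 3 * base)
  expect_equal(icer(1234.5, 2 * 0.37)$value_exact, base / 2)
})

test_that("published incremental costs and effect gains reproduce the printed ICERs", {
  t4 <- table4_printed()
  # cost-per-QALY consistent for three strata; female-diabetes differs by $1
  for (i in 1:3)
    expect_equal(icer(t4$incremental_cost[i], t4$delta_qaly[i])$value,
                 t4$cost_per_qaly[i])
  expect_equal(icer(t4$incremental_cost[4], t4$delta_qaly[4])$value,
               t4$cost_per_qaly[4] + 1)
  # cost-per-life-year consistent for all four strata
  for (i in 1:4)
    expect_equal(icer(t4$incremental_cost[i], t4$delta_ly[i])$value,
                 t4$cost_per_ly[i])
})

test_that("scenario comparison assembles a consistent record", {
  s <- model_states()
  zero_states <- stats::setNames(rep(0, 5), s)
  zero_events <- matrix(0, 5, 5, dimnames = list(s, s))
  sched <- cost_schedule(state_costs = zero_states, event_costs = zero_events,
                         program_cost = 1215, placeholder = FALSE)
  sched0 <- cost_schedule(state_costs = zero_states, event_costs = zero_events,
                          program_cost = 0, placeholder = FALSE)
  tr <- healthy_forever_trace()
  run_a <- list(trace = tr, costs = expected_costs(tr, sched))
  run_b <- list(trace = tr, costs = expected_costs(tr, sched0))

  # identical runs: zero deltas, ICER suppressed
  same <- compare_scenarios(run_a, run_a)
  expect_equal(same$delta_qaly, 0)
  expect_equal(same$incremental_cost, 0)
  expect_true(is.na(same$cost_per_qaly))
  expect_equal(same$flag_qaly, "cost-saving")

  # dominance: cheaper and (weakly) more effective intervention
  st <- default_stratum_profiles()[1, ]
  tm_iv <- suppressWarnings(build_transition_matrix(st, scenario_spec("intervention")))
  tr_iv <- run_cohort(tm_iv, simulation_settings())
  tm_cf <- suppressWarnings(build_transition_matrix(st, scenario_spec("counterfactual")))
  tr_cf <- run_cohort(tm_cf, simulation_settings())
  dom <- compare_scenarios(list(trace = tr_iv, costs = expected_costs(tr_iv, sched0)),
                           list(trace = tr_cf, costs = expected_costs(tr_cf, sched)))
  expect_gt(dom$delta_qaly, 0)
  expect_lt(dom$incremental_cost, 0)
  expect_equal(dom$flag_qaly, "cost-saving")

  # mismatched settings are rejected
  tr5 <- healthy_forever_trace(horizon = 5)
  expect_error(compare_scenarios(run_a,
                                 list(trace = tr5,
                                      costs = expected_costs(tr5, sched0))),
               class = "markovcea_config_error")
})

test_that("LTC break-even follows the offset formula", {
  expect_equal(ltc_breakeven(0, 2540, 27.6), 0)
  expect_equal(ltc_breakeven(8344, 2540, 27.6), 8344 / (2540 * 27.6))
  expect_equal(round(ltc_breakeven(8344, 2540, 27.6), 3), 0.119)
  # a single ~3.3-month stay fully offsets the incremental cost
  expect_equal(ltc_breakeven(8344, 2540, 3.285), 1, tolerance = 1e-4)
  expect_error(ltc_breakeven(8344, 0, 27.6), class = "markovcea_config_error")
  expect_error(ltc_breakeven(8344, 2540, -1), class = "markovcea_config_error")
})
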