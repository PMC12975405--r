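test_that("degenerate runs hit their closed-form totals", {
  I5 <- diag(5); dimnames(I5) <- list(model_states(), model_states())
  tm <- validate_matrix(transition_matrix(I5), policy = "error")$matrix

  # all-death start accrues nothing
  dead <- simulation_settings(horizon = 20, discount_rate = 0,
                              start = c(0, 0, 0, 0, 1))
  tr0 <- run_cohort(tm, dead)
  expect_equal(discounted_qalys(tr0), 0)
  expect_equal(discounted_life_years(tr0), 0)

  # healthy forever, no discounting: LY = horizon, QALY = 0.85 * horizon
  tr <- run_cohort(tm, simulation_settings(horizon = 20, discount_rate = 0))
  expect_equal(discounted_life_years(tr), 20)
  expect_equal(discounted_qalys(tr), 17)

  # 3% discount, cycle-start rewards: the geometric series
  # sum_{t=0..19} 1.03^-t = (1 - 1.03^-20) / (1 - 1.03^-1)
  trd <- run_cohort(tm, simulation_settings(horizon = 20, discount_rate = 0.03,
                                            reward_timing = "cycle-start"))
  af <- annuity_factor(0.03, 20)
  expect_equal(discounted_life_years(trd), af, tolerance = 1e-9)
  expect_equal(discounted_qalys(trd), 0.85 * af, tolerance = 1e-9)
  expect_equal(round(discounted_life_years(trd), 4), 15.3238)
  expect_equal(round(discounted_qalys(trd), 4), 13.0252)

  # totals agree with recomputation from the per-cycle increments
  expect_equal(discounted_qalys(trd), sum(trd$qaly_increments), tolerance = 1e-9)
  expect_equal(discounted_life_years(trd), sum(trd$ly_increments),
               tolerance = 1e-9)
})

test_that("utilities bound QALYs by life years", {
  set.seed(401)
  ones <- utility_weights(healthy = 1, stroke = 1, mi = 1, chf = 1)
  for (k in 1:25) {
    tm <- random_valid_matrix()
    tr <- run_cohort(tm, simulation_settings())
    expect_lte(discounted_qalys(tr), discounted_life_years(tr) + 1e-12)
    expect_lte(discounted_life_years(tr),
               tr$settings$horizon * tr$settings$cycle_length)
    tr1 <- run_cohort(tm, simulation_settings(), utilities = ones)
    expect_equal(discounted_qalys(tr1), discounted_life_years(tr1),
                 tolerance = 1e-12)
  }
})

test_that("mass is conserved and death is monotone", {
  set.seed(402)
  for (k in 1:25) {
    tr <- run_cohort(random_valid_matrix(), simulation_settings())
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 21), tolerance = 1e-12)
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-15))
    # flows out of each state match that state's occupancy
    expect_equal(apply(tr$flows, c(1, 2), sum),
                 tr$occupancy[1:20, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("engine agrees with the matrix-power oracle on random matrices", {
  set.seed(403)
  for (k in 1:50) {
    tm <- random_valid_matrix()
    timing <- sample(c("cycle-start", "cycle-end", "half-cycle"), 1)
    settings <- simulation_settings(horizon = sample(5:30, 1),
                                    discount_rate = stats::runif(1, 0, 0.08),
                                    reward_timing = timing)
    tr <- run_cohort(tm, settings)
    o <- matrix_power_oracle(tm, settings)
    expect_equal(discounted_qalys(tr), o$qalys, tolerance = 1e-9)
    expect_equal(discounted_life_years(tr), o$life_years, tolerance = 1e-9)
  }
})

test_that("totals fall strictly as the discount rate rises", {
  set.seed(404)
  tm <- random_valid_matrix()
  rates <- c(0, 0.01, 0.03, 0.05, 0.10)
  q <- vapply(rates, function(r)
    discounted_qalys(run_cohort(tm, simulation_settings(discount_rate = r))),
    numeric(1))
  l <- vapply(rates, function(r)
    discounted_life_years(run_cohort(tm, simulation_settings(discount_rate = r))),
    numeric(1))
  expect_true(all(diff(q) < 0))
  expect_true(all(diff(l) < 0))
})

test_that("shifting healthy-row mass from death to healthy never costs life years", {
  set.seed(405)
  for (k in 1:10) {
    tm <- random_valid_matrix()
    shifted <- tm$probs
    d <- shifted["healthy", "death"]
    eps <- d * stats::runif(1)
    shifted["healthy", "death"] <- d - eps
    shifted["healthy", "healthy"] <- shifted["healthy", "healthy"] + eps
    tm2 <- validate_matrix(transition_matrix(shifted), policy = "error")$matrix
    expect_gte(discounted_life_years(run_cohort(tm2, simulation_settings())),
               discounted_life_years(run_cohort(tm, simulation_settings())) - 1e-12)
  }
})

test_that("raising one healthy-row event probability never gains life years", {
  st <- default_stratum_profiles()[1, ]
  base <- suppressWarnings(
    build_transition_matrix(st, scenario_spec("counterfactual"),
                            policy = "residual_to_self"))
  ly0 <- discounted_life_years(run_cohort(base, simulation_settings()))
  for (ev in c("stroke", "mi", "chf", "death")) {
    P <- base$probs
    P["healthy", ev] <- P["healthy", ev] + 0.02
    P["healthy", "healthy"] <- P["healthy", "healthy"] - 0.02
    tm <- validate_matrix(transition_matrix(P), policy = "error")$matrix
    expect_lte(discounted_life_years(run_cohort(tm, simulation_settings())),
               ly0 + 1e-12)
  }
})

test_that("engine rejects unvalidated matrices and bad settings", {
  expect_error(run_cohort(table2_matrix(), simulation_settings()),
               "validated", class = "markovcea_config_error")
  expect_error(simulation_settings(horizon = 0), class = "markovcea_config_error")
  expect_error(simulation_settings(discount_rate = -0.01),
               class = "markovcea_config_error")
  expect_error(simulation_settings(start = c(0.5, 0, 0, 0, 0)),
               class = "markovcea_config_error")
})

test_that("six-state matrices from the extra-state policy run end to end", {
  vx <- validate_matrix(table2_matrix(), policy = "residual_to_extra_state",
                        extra_state = "post_stroke")$matrix
  u <- utility_weights(post_stroke = 0.65)
  settings <- simulation_settings(start = c(1, 0, 0, 0, 0, 0))
  tr <- run_cohort(vx, settings, utilities = u)
  o <- matrix_power_oracle(vx, settings, utilities = u)
  expect_equal(discounted_qalys(tr), o$qalys, tolerance = 1e-9)
  expect_equal(unname(rowSums(tr$occupancy)), rep(1, 21), tolerance = 1e-12)
})

test_that("age-updating matrices shorten survival relative to frozen entry age", {
  st <- default_stratum_profiles()[1, ]
  settings <- simulation_settings()
  frozen <- suppressWarnings(
    build_transition_matrix(st, scenario_spec("counterfactual")))
  aging <- suppressWarnings(
    build_transition_matrices_aging(st, scenario_spec("counterfactual"),
                                    horizon = settings$horizon))
  expect_length(aging, 20)
  # first-cycle matrix equals the time-homogeneous one at entry age
  expect_equal(aging[[1]]$probs, frozen$probs, tolerance = 1e-12)
  # later matrices carry strictly higher exit risk from healthy
  leave <- vapply(aging, function(m) 1 - m$probs["healthy", "healthy"],
                  numeric(1))
  expect_true(all(diff(leave) > 0))
  tr_frozen <- run_cohort(frozen, settings)
  tr_aging <- run_cohort(aging, settings)
  expect_lt(discounted_life_years(tr_aging), discounted_life_years(tr_frozen))
  expect_equal(unname(rowSums(tr_aging$occupancy)), rep(1, 21),
               tolerance = 1e-12)
  # per-cycle list must match the horizon
  expect_error(run_cohort(aging[1:5], settings), class = "markovcea_config_error")
})

test_that("trace tables export one row per cycle", {
  tr <- run_cohort(validate_matrix(table2_matrix(),
                                   policy = "residual_to_self")$matrix,
                   simulation_settings())
  tab <- trace_table(tr)
  expect_equal(nrow(tab), 20)
  expect_equal(tab$cycle, 1:20)
  expect_equal(sum(tab$qaly_increment), discounted_qalys(tr), tolerance = 1e-9)
  path <- withr::local_tempfile(fileext = ".tsv")
  trace_table(tr, path)
  expect_equal(nrow(utils::read.delim(path)), 20)
})
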