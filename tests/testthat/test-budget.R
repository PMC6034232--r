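test_that("the epidemiology funnel reproduces the published eligible counts", {
  el <- eligible_population()
  expect_equal(el$intermediate, 140)
  expect_equal(el$advanced, 870)
  expect_equal(el$total, 1010)
  expect_equal(el$eligible_fraction, 0.149 * 0.095 + 0.305 * 0.288)
  expect_equal(round(100 * el$eligible_fraction, 1), 10.2)
  expect_equal(el$intermediate_advanced_share, 0.454)
  zero <- eligible_population(epidemiology_funnel(incidence = 0))
  expect_equal(zero$total, 0)
})

test_that("prevalence matches a closed-form sum for exponential survival", {
  # exponential OS with 12-month median: alive share at month m is
  # exp(-log(2) m / 12); prevalence is the analytic cohort-sum
  lam <- log(2) / 12
  f <- make_survival_fit("exponential", list(rate = lam))
  sch <- transition_schedule(f, f, horizon_cycles = 480)
  tr <- run_cohort(sch)
  traces <- list("TARE.intermediate" = tr, "sorafenib.intermediate" = tr,
                 "TARE.advanced" = tr, "sorafenib.advanced" = tr)
  el <- eligible_population()
  for (census in c("year_end", "mid_year", "year_start")) {
    offset <- switch(census, year_end = 0, mid_year = 6, year_start = 12)
    analytic <- 1010 * sum(exp(-lam * (12 * (1:20) - offset)))
    got <- steady_state_prevalence(traces, el, census = census)
    expect_equal(got, tarebia:::round_half_up(analytic), tolerance = 1e-9)
  }
})

test_that("prevalence requires traces long enough for the cohort stack", {
  f <- make_survival_fit("exponential", list(rate = 0.05))
  sch <- transition_schedule(f, f, horizon_cycles = 24)
  tr <- run_cohort(sch)
  traces <- list("TARE.intermediate" = tr, "sorafenib.intermediate" = tr,
                 "TARE.advanced" = tr, "sorafenib.advanced" = tr)
  expect_error(steady_state_prevalence(traces), "20 years")
})

test_that("identical future and baseline shares produce zero savings", {
  sc <- market_scenario(baseline = 0.2, shares = rep(0.2, 5))
  pb <- project_budget(sc, fixture_bia$traces)
  expect_equal(pb$savings, rep(0, 5), tolerance = 1e-9)
  expect_equal(pb$cumulative_savings, rep(0, 5), tolerance = 1e-9)
})

test_that("budgets are linear in the eligible cohort size", {
  el <- eligible_population()
  el2 <- el; el2$intermediate <- 2 * el$intermediate
  el2$advanced <- 2 * el$advanced; el2$total <- 2 * el$total
  p1 <- project_budget(market_scenario(), fixture_bia$traces, el)
  p2 <- project_budget(market_scenario(), fixture_bia$traces, el2)
  expect_equal(p2$budget, 2 * p1$budget, tolerance = 1e-12)
  expect_equal(p2$savings, 2 * p1$savings, tolerance = 1e-12)
})

test_that("yearly savings are non-decreasing under the default ramp", {
  sv <- fixture_bia$budget$savings
  expect_true(all(diff(sv) > 0))
  expect_equal(fixture_bia$budget$cumulative_savings, cumsum(sv))
})

test_that("a hand-computable two-state toy model is matched to the cent", {
  # 1-year survival; TARE costs 100 EUR in its only year, sorafenib 150;
  # 10 eligible patients per stage per year; share flips 0 -> 1
  traces <- list(
    "TARE.intermediate" = toy_trace(100, 1),
    "sorafenib.intermediate" = toy_trace(150, 1),
    "TARE.advanced" = toy_trace(100, 1),
    "sorafenib.advanced" = toy_trace(150, 1))
  el <- list(intermediate = 10, advanced = 10, total = 20)
  sc <- market_scenario(baseline = 0, shares = rep(1, 5))
  pb <- project_budget(sc, traces, el, n_prevalent_cohorts = 2)
  # each year: 20 incident patients all switch from 150 to 100 EUR
  expect_equal(pb$savings, rep(20 * 50, 5))
  expect_equal(pb$cumulative_savings[5], 5000)
  # budget itself: only the incident cohort is alive (1-year survival),
  # so the scenario budget is 20 x 100 each year, to the cent
  expect_equal(pb$budget, rep(2000, 5))
  expect_equal(pb$budget_baseline, rep(3000, 5))
})

test_that("steady-state hospitalization delta matches the share arithmetic", {
  deltas <- fixture_bia$deltas
  expect_equal(deltas$extra_hospitalizations[5],
               0.30 * 140 * (0.194 - 0.174) + 0.30 * 870 * (0.43 - 0.31),
               tolerance = 1e-12)
  expect_equal(round(deltas$extra_hospitalizations[5]), 32)
  # held at 50% TARE from year 5 on
  expect_equal(deltas$extra_hospitalizations[10],
               deltas$extra_hospitalizations[5])
  # identical rates in both arms would zero the delta
  proto <- default_protocol()
  proto$decompensation$TARE <- proto$decompensation$sorafenib
  d2 <- outcome_deltas(market_scenario(), fixture_bia$traces, proto,
                       years = 5)
  expect_equal(d2$extra_hospitalizations, rep(0, 5))
})

test_that("death deltas cancel when both arms share one survival curve", {
  f <- make_survival_fit("exponential", list(rate = 0.05))
  sch <- transition_schedule(f, f, horizon_cycles = 480)
  tr <- run_cohort(sch)
  traces <- list("TARE.intermediate" = tr, "sorafenib.intermediate" = tr,
                 "TARE.advanced" = tr, "sorafenib.advanced" = tr)
  d <- outcome_deltas(market_scenario(), traces, years = 6)
  expect_equal(d$deaths_avoided, rep(0, 6), tolerance = 1e-9)
})

test_that("scenario overrides are validated and identity-stable", {
  base <- scenario_override(list())
  expect_equal(base$budget$cumulative_savings,
               fixture_bia$budget$cumulative_savings, tolerance = 1e-12)
  expect_error(scenario_override(list(discount_rate = 0.03)),
               "unknown override")
})
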