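catalog <- default_cost_catalog()
protocol <- default_protocol()

test_that("the quarterly follow-up round sums the tariff catalogue", {
  expect_equal(lab_panel_cost(catalog), 34.20)
  expect_equal(quarterly_followup_cost(catalog), 17.90 + 137.23 + 34.20)
  zero <- catalog; zero[] <- 0
  expect_equal(quarterly_followup_cost(zero), 0)
  # linearity in a single item
  up <- default_cost_catalog(overrides = list(ct = 2 * 137.23))
  expect_equal(quarterly_followup_cost(up) - quarterly_followup_cost(catalog),
               137.23)
  broken <- catalog[setdiff(names(catalog), "ct")]
  class(broken) <- "cost_catalog"
  expect_error(quarterly_followup_cost(broken), "missing cost.*ct")
})

test_that("first-line streams reproduce the printed tariff arithmetic", {
  fl <- first_line_cost_stream("TARE", "intermediate", catalog, protocol)
  # procedure component: simulation + 1.1 procedures x TARE tariff
  expect_equal(4052 + 1.1 * 9510, 14513)
  expect_equal(fl$amount[1], 14513 + 22.50 + 34.20)
  expect_equal(fl$amount[2], 189.33)  # one-month check
  # sorafenib nominal drug component: duration x monthly tariff
  expect_equal(protocol$sorafenib_duration[["advanced"]] *
                 catalog[["sorafenib_monthly"]], 30674.70)
  pfs <- fixture_fits$sorafenib$advanced$pfs
  fs <- first_line_cost_stream("sorafenib", "advanced", catalog, protocol,
                               pfs_fit = pfs)
  drug <- fs[fs$basis == "stable_cont", ]
  expect_equal(drug$amount, 3787)
  # zero-duration sorafenib: no drug charge accrues in the cohort
  expect_error(first_line_cost_stream("chemo", "advanced"), "unknown arm")
})

test_that("the payment-by-result refund follows the stated rule", {
  expect_equal(expected_refund(1, 3787), 0)
  expect_equal(expected_refund(0.8, 3787), 1514.80)
  expect_equal(expected_refund(0, 3787), 2 * 3787)
  fit <- make_survival_fit("exponential", list(rate = 0.1))
  expect_equal(expected_refund(fit, 3787),
               (1 - exp(-0.2)) * 2 * 3787, tolerance = 1e-12)
  # never exceeds two monthly packages
  expect_lte(expected_refund(0, 3787), 2 * 3787)
})

test_that("progression-entry costs match the second-line share arithmetic", {
  expect_equal(progression_entry_cost("sorafenib", "intermediate", catalog,
                                      protocol),
               0.066 * 4052 + 0.105 * 7549, tolerance = 1e-9)
  expect_equal(0.066 * 4052 + 0.105 * 7549, 1060.08, tolerance = 0.005)
  no_sor <- progression_entry_cost("TARE", "advanced", catalog, protocol,
                                   include_second_line_sorafenib = FALSE)
  expect_equal(no_sor, 0.022 * 4052 + 0.022 * 4041, tolerance = 1e-9)
  expect_equal(0.022 * 4052 + 0.022 * 4041, 178.05, tolerance = 0.005)
  # with the second-line sorafenib component (duration defaults to the
  # stage's first-line duration)
  full <- progression_entry_cost("TARE", "advanced", catalog, protocol)
  expect_equal(full, no_sor + 0.20 * 8.1 * 3787, tolerance = 1e-9)
  zero <- catalog; zero[] <- 0
  expect_equal(progression_entry_cost("TARE", "advanced", zero, protocol), 0)
})

test_that("decompensation streams carry the printed expected totals", {
  ae <- adverse_event_cost("TARE", "advanced", catalog, protocol)
  expect_equal(attr(ae, "nominal_total"), 0.43 * 1688)
  expect_equal(0.43 * 1688, 725.84)
  expect_equal(sum(ae$amount * (ae$cycle_to - ae$cycle_from + 1)), 725.84)
  ae2 <- adverse_event_cost("sorafenib", "intermediate", catalog, protocol)
  expect_equal(attr(ae2, "nominal_total"), 293.712, tolerance = 1e-9)
})

test_that("transplant costing matches the tariff arithmetic", {
  ts <- transplant_cost_stream(catalog)
  entry <- ts[ts$basis == "transplant_inflow", ]
  maint <- ts[ts$basis == "transplant_cont", ]
  expect_equal(entry$amount, 68027)
  expect_equal(maint$amount, 6229 / 12)
  # one transplanted patient surviving 24 months after surgery
  expect_equal(entry$amount + 24 * maint$amount, 68027 + 2 * 6229)
  expect_equal(0.037 * entry$amount, 2517, tolerance = 0.005)
})

test_that("cost streams are linear in the catalogue and additive by category", {
  pfs <- fixture_fits$sorafenib$intermediate$pfs
  base <- build_cost_streams("sorafenib", "intermediate", catalog, protocol,
                             pfs_fit = pfs)
  doubled_cat <- catalog; doubled_cat[] <- 2 * unclass(catalog)
  class(doubled_cat) <- "cost_catalog"
  doubled <- build_cost_streams("sorafenib", "intermediate", doubled_cat,
                                protocol, pfs_fit = pfs)
  expect_equal(doubled$amount, 2 * base$amount)
  expect_setequal(unique(base$category),
                  c("first_line", "followup", "subsequent", "adverse_event"))
  # transplant only for intermediate TARE
  tare_int <- build_cost_streams("TARE", "intermediate", catalog, protocol)
  expect_true("transplant" %in% tare_int$category)
  tare_adv <- build_cost_streams("TARE", "advanced", catalog, protocol)
  expect_false("transplant" %in% tare_adv$category)
})

test_that("catalogue and protocol overrides are validated", {
  expect_error(default_cost_catalog(overrides = list(nonexistent = 5)),
               "unknown cost")
  expect_error(default_cost_catalog(overrides = list(ct = -1)),
               "non-negative")
  p2 <- default_protocol(overrides = list(tare_procedures = 1.5))
  expect_equal(unname(p2$tare_procedures), c(1.5, 1.5))
  expect_error(default_protocol(overrides = list(bogus = 1)),
               "unknown protocol")
  # the documented alternative sorafenib tariff is accepted
  alt <- default_cost_catalog(overrides = list(sorafenib_monthly = 3536.17))
  expect_equal(alt[["sorafenib_monthly"]], 3536.17)
})
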