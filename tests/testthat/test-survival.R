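test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring at t = 2 removes a patient from the risk set without a step
  km2 <- km_curve(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  expect_equal(km2$n_risk[km2$time == 3], 1)
  # all censored: flat at 1
  km3 <- km_curve(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(km3$surv == 1))
  expect_error(km_curve(numeric(0), logical(0)), "no observations")
})

test_that("maximum likelihood recovers parameters from censored data", {
  set.seed(42)
  x <- stats::rexp(5000, rate = 0.1)
  fit <- fit_parametric(x, rep(TRUE, 5000), "exponential")
  expect_lt(abs(fit$params$rate - 0.1) / 0.1, 0.05)
  # the Weibull family nests the exponential: shape ~ 1
  fw <- fit_parametric(x, rep(TRUE, 5000), "weibull")
  expect_lt(abs(fw$params$shape - 1), 0.05)
  # under right censoring
  cens <- pmin(x, 15)
  fit_c <- fit_parametric(cens, x <= 15, "exponential")
  expect_lt(abs(fit_c$params$rate - 0.1) / 0.1, 0.05)
})

test_that("parameter recovery holds across families and seeds", {
  n <- 2000
  ok <- matrix(NA, 50, 2)
  for (s in 1:50) {
    set.seed(1000 + s)
    # weibull truth
    xw <- stats::rweibull(n, shape = 1.4, scale = 18)
    cw <- pmin(xw, 84)
    fw <- fit_parametric(cw, xw <= 84, "weibull")
    ok[s, 1] <- abs(fw$params$shape - 1.4) / 1.4 <= 0.1 &&
      abs(fw$params$scale - 18) / 18 <= 0.1
    # lognormal truth
    xl <- stats::rlnorm(n, meanlog = 2.5, sdlog = 0.8)
    cl <- pmin(xl, 84)
    fl <- fit_parametric(cl, xl <= 84, "lognormal")
    ok[s, 2] <- abs(fl$params$meanlog - 2.5) / 2.5 <= 0.1 &&
      abs(fl$params$sdlog - 0.8) / 0.8 <= 0.1
  }
  expect_gte(mean(ok[, 1]), 0.9)
  expect_gte(mean(ok[, 2]), 0.9)
})

test_that("fitted laws agree with an independent implementation", {
  skip_if_not_installed("flexsurv")
  set.seed(8)
  x <- stats::rweibull(800, shape = 1.3, scale = 20)
  ev <- x <= 60
  xc <- pmin(x, 60)
  ours <- fit_parametric(xc, ev, "weibull")
  ref <- flexsurv::flexsurvreg(survival::Surv(xc, ev) ~ 1, dist = "weibull")
  expect_equal(ours$params$shape, unname(ref$res["shape", "est"]),
               tolerance = 1e-4)
  expect_equal(ours$params$scale, unname(ref$res["scale", "est"]),
               tolerance = 1e-4)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("degenerate inputs never produce silent garbage", {
  expect_error(fit_parametric(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               "at least two events")
  expect_error(fit_parametric(c(1, 2), c(TRUE, TRUE), "gompertz"),
               "unsupported family")
})

test_that("AIC selection prefers the generating family and breaks ties fixedly", {
  one <- make_survival_fit("weibull", list(shape = 2, scale = 10))
  expect_identical(select_best_fit(list(one)), one)
  set.seed(5)
  x <- stats::rweibull(2000, shape = 2, scale = 12)
  fits <- list(fit_parametric(x, rep(TRUE, 2000), "exponential"),
               fit_parametric(x, rep(TRUE, 2000), "weibull"))
  expect_equal(select_best_fit(fits)$family, "weibull")
  # identical AIC duplicates: first by family order
  a <- new_fit_for_test <- fit_parametric(x, rep(TRUE, 2000), "weibull")
  b <- a; b$family <- "loglogistic"
  expect_equal(select_best_fit(list(b, a))$family, "weibull")
  expect_error(select_best_fit(list()), "no candidate")
})

test_that("restricted mean survival matches closed forms and calibration", {
  exp_fit <- make_survival_fit("exponential", list(rate = 0.25))
  expect_equal(restricted_mean_survival(exp_fit, Inf), 4, tolerance = 1e-6)
  expect_equal(restricted_mean_survival(exp_fit, 0), 0)
  # finite-horizon closed form (1 - exp(-rate h)) / rate
  expect_equal(restricted_mean_survival(exp_fit, 10),
               (1 - exp(-2.5)) / 0.25, tolerance = 1e-6)
  cal <- fixture_fits$sorafenib$advanced$os
  expect_equal(restricted_mean_survival(cal, Inf), 16.1, tolerance = 1e-4)
})

test_that("survival functions satisfy the axioms for every family", {
  fits <- list(
    make_survival_fit("exponential", list(rate = 0.2)),
    make_survival_fit("weibull", list(shape = 1.5, scale = 12)),
    make_survival_fit("loglogistic", list(shape = 2, scale = 9)),
    make_survival_fit("lognormal", list(meanlog = 2, sdlog = 0.7)))
  tt <- seq(0, 600, by = 0.5)
  for (f in fits) {
    s <- surv_prob(f, tt)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 0))
    expect_lt(s[length(s)], 1e-2)
    expect_true(all(s >= 0 & s <= 1))
  }
})
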