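test_that("propensity coefficients are recovered on simulated assignment", {
  cfg <- cohort_config(
    centers = list(c(tare = 2500, sorafenib = 2500)),
    assignment = c(intercept = 0, pvt = 1.0, child_pugh_b = 0,
                   multinodular = 0),
    fixed_arm_counts = FALSE)
  reg <- generate_registry(cfg, seed = 7)
  m <- fit_propensity(reg)
  expect_lt(abs(m$coefficients[["pvt"]] - 1.0), 0.1)
  expect_lt(abs(m$coefficients[["child_pugh"]]), 0.1)
})

test_that("near-independent assignment yields near-zero coefficients", {
  cfg <- cohort_config(
    centers = list(c(tare = 3000, sorafenib = 3000)),
    assignment = c(intercept = 0.4, pvt = 0, child_pugh_b = 0,
                   multinodular = 0),
    fixed_arm_counts = FALSE)
  reg <- generate_registry(cfg, seed = 3)
  m <- fit_propensity(reg)
  expect_true(all(abs(m$coefficients[-1]) < 0.1))
  expect_equal(mean(m$score), mean(reg$arm == "TARE"), tolerance = 1e-6)
})

test_that("degenerate registries are rejected", {
  single_arm <- tiny_registry(os = c(5, 6, 7), death = rep(TRUE, 3),
                              arm = "TARE")
  expect_error(fit_propensity(single_arm), "two patients per arm")
})

test_that("identical score multisets with an infinite caliper match everyone", {
  sc <- rep(c(0.2, 0.4, 0.6), 2)
  m <- fake_ps_model(sc, rep(c("TARE", "sorafenib"), each = 3))
  mp <- match_pairs(m, caliper = Inf)
  expect_equal(nrow(mp$pairs), 3)
  expect_equal(mp$pairs$distance, rep(0, 3))
  expect_length(mp$discarded, 0)
})

test_that("small matchings agree with the exhaustive optimum", {
  # 3 TARE vs 2 sorafenib with hand-set scores; enumerate every 1:1
  # assignment and minimize total logit distance
  scores <- c(0.9, 0.5, 0.2, 0.88, 0.52)
  arms <- c("TARE", "TARE", "TARE", "sorafenib", "sorafenib")
  m <- fake_ps_model(scores, arms)
  lt <- stats::qlogis(scores)
  trt <- which(arms == "TARE"); ctl <- which(arms != "TARE")
  best <- NULL; best_cost <- Inf
  for (perm in list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))) {
    cost <- sum(abs(lt[trt[perm]] - lt[ctl]))
    if (cost < best_cost) {
      best_cost <- cost
      best <- data.frame(tare = m$patient_id[trt[perm]],
                         ctl = m$patient_id[ctl])
    }
  }
  mp <- match_pairs(m, caliper = Inf)
  got <- mp$pairs[order(mp$pairs$sorafenib_id), ]
  want <- best[order(best$ctl), ]
  expect_equal(got$tare_id, want$tare)
  expect_equal(got$sorafenib_id, want$ctl)
})

test_that("caliper is enforced and validated", {
  m <- fake_ps_model(c(0.9, 0.1), c("TARE", "sorafenib"))
  expect_error(match_pairs(m, caliper = 0), "caliper")
  expect_error(match_pairs(m, caliper = -1), "caliper")
  mp <- match_pairs(m, caliper = 0.5)  # logit distance ~4.4 > caliper
  expect_equal(nrow(mp$pairs), 0)
  expect_length(mp$discarded, 2)
})

test_that("no patient is reused and matched arms have equal size", {
  reg <- generate_registry(seed = 21)
  mp <- match_pairs(fit_propensity(reg))
  ids <- c(mp$pairs$tare_id, mp$pairs$sorafenib_id)
  expect_equal(anyDuplicated(ids), 0)
  sub <- matched_registry(reg, mp)
  expect_equal(sum(sub$arm == "TARE"), sum(sub$arm == "sorafenib"))
  expect_true(all(mp$pairs$distance <= mp$caliper))
})

test_that("matched treated set is invariant to monotone score rescaling", {
  reg <- generate_registry(seed = 4)
  m1 <- fit_propensity(reg)
  # strictly increasing transform of the scores
  m2 <- m1
  m2$score <- m1$score^3
  m2$logit <- stats::qlogis(m2$score)
  p1 <- match_pairs(m1, caliper = Inf)
  p2 <- match_pairs(m2, caliper = Inf)
  expect_equal(nrow(p1$pairs), nrow(p2$pairs))
  expect_setequal(p1$pairs$tare_id, p2$pairs$tare_id)
})

test_that("balance improves under confounding, without division by zero", {
  # identical groups: all SMDs zero
  both <- rbind(tiny_registry(os = c(5, 6), death = c(TRUE, TRUE),
                              arm = "TARE"),
                tiny_registry(os = c(5, 6), death = c(TRUE, TRUE)))
  both$patient_id <- sprintf("B-%03d", seq_len(nrow(both)))
  class(both) <- c("hcc_registry", "data.frame")
  m0 <- fake_ps_model(rep(0.5, 4), both$arm, ids = both$patient_id)
  mp0 <- match_pairs(m0, caliper = Inf)
  bt0 <- balance_table(both, mp0)
  expect_equal(bt0$smd_before, rep(0, 3))
  expect_equal(bt0$smd_after, rep(0, 3))  # constant covariates, no NaN
  # strong PVT confounding: post-match SMD(pvt) below pre-match
  reg <- generate_registry(seed = 17)
  mp <- match_pairs(fit_propensity(reg))
  bt <- balance_table(reg, mp)
  pvt <- bt[bt$covariate == "pvt", ]
  expect_lt(pvt$smd_after, pvt$smd_before)
})

test_that("matching reduces mean SMD across seeds", {
  improved <- vapply(1:20, function(s) {
    reg <- generate_registry(seed = 100 + s)
    mp <- match_pairs(fit_propensity(reg))
    bt <- balance_table(reg, mp)
    c(mean(bt$smd_before), mean(bt$smd_after))
  }, numeric(2))
  expect_lt(mean(improved[2, ]), mean(improved[1, ]))
})
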