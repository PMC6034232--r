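# Shared fixtures: one calibrated deterministic analysis reused across files.

fixture_fits <- calibrated_fits()
fixture_bia <- bia_analysis(fits = fixture_fits)

# quadrature oracle for the mean of a survival law, independent of the
# package's RMST path
oracle_mean <- function(surv_fn) {
  stats::integrate(surv_fn, 0, Inf, rel.tol = 1e-10,
                   subdivisions = 2000L)$value
}

# single-group registry configuration (one centre, one arm/stage)
one_group_config <- function(n, arm = "sorafenib", stage = "advanced",
                             censor_horizon = 1e6) {
  cohort_config(
    centers = list(c(tare = if (arm == "TARE") n else 0,
                     sorafenib = if (arm == "sorafenib") n else 0)),
    pvt_prevalence = if (stage == "advanced") 1 else 0,
    censor_horizon = censor_horizon)
}

# hand-built registry rows for degenerate-input tests
tiny_registry <- function(os, death, arm = "sorafenib",
                          stage = "intermediate", pfs = os,
                          prog = death) {
  n <- length(os)
  structure(data.frame(
    patient_id = sprintf("T-%03d", seq_len(n)), center = 1L,
    stage = stage, child_pugh = "A", nodules = "single",
    pvt = stage == "advanced", arm = arm,
    pfs_months = pfs, os_months = os,
    prog_event = prog, death_event = death,
    stringsAsFactors = FALSE), class = c("hcc_registry", "data.frame"))
}

# hand-built propensity model (for matching tests with fixed scores)
fake_ps_model <- function(scores, arms, ids = sprintf("P-%03d",
                                                      seq_along(scores))) {
  structure(list(coefficients = NULL, score = scores,
                 logit = stats::qlogis(scores), patient_id = ids,
                 arm = arms), class = "propensity_model")
}

# minimal hand-built markov_trace: one-off yearly costs, step survival
toy_trace <- function(yearly_cost, alive_years, horizon_years = 30) {
  H <- horizon_years * 12L
  occ <- matrix(0, H + 1, 4,
                dimnames = list(NULL, c("stable", "progression",
                                        "transplant", "dead")))
  alive <- c(1, as.numeric((seq_len(H) / 12) <= alive_years))
  occ[, "stable"] <- alive
  occ[, "dead"] <- 1 - alive
  costs <- matrix(0, H, 5,
                  dimnames = list(NULL, c("first_line", "followup",
                                          "subsequent", "adverse_event",
                                          "transplant")))
  for (a in seq_along(yearly_cost))
    costs[12 * (a - 1) + 1, "first_line"] <- yearly_cost[a]
  structure(list(occupancy = occ,
                 flows = matrix(0, H, 4,
                                dimnames = list(NULL,
                                  c("stable_prog", "stable_death",
                                    "stable_transplant", "prog_death"))),
                 costs = costs, cycle_months = 1),
            class = "markov_trace")
}
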