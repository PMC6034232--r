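# Default end-to-end run configuration.
registry:
  centers:
    - {tare: 288, sorafenib: 125}
    - {tare: 38, sorafenib: 42}
    - {tare: 63, sorafenib: 74}
  pvt_prevalence: 0.40
  child_pugh_b_prevalence: 0.25
  multinodular_prevalence: 0.60
  assignment: {intercept: 0.5, pvt: -1.4, child_pugh_b: -0.5, multinodular: -0.3}
  fixed_arm_counts: true
  censor_horizon: 84
matching:
  caliper_sd: 0.2
survival:
  families: [exponential, weibull, loglogistic, lognormal]
model:
  cycle_months: 1
  horizon_cycles: 480
  death_attribution: progression_first
  census: year_end
costs:
  overrides: {}
protocol:
  overrides: {}
funnel:
  incidence: 13200
  hcc_fraction: 0.75
  stage_shares: {intermediate: 0.149, advanced: 0.305}
  eligibility: {intermediate: 0.095, advanced: 0.288}
scenario:
  baseline: 0.20
  shares: [0.30, 0.30, 0.40, 0.40, 0.50]
years: 5
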