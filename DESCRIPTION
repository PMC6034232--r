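Package: tarebia
Title: Budget Impact Modelling of Radioembolization Versus Sorafenib in
    Intermediate-Advanced Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model and national budget impact
    analysis comparing trans-arterial radioembolization (TARE) with sorafenib
    for intermediate and advanced hepatocellular carcinoma. Provides a
    synthetic patient-registry generator calibrated to published survival
    summaries, propensity-score matching, Kaplan-Meier and parametric survival
    fitting under right censoring, conversion of overall and progression-free
    survival curves into per-cycle transition probabilities, per-patient cost
    accounting from a DRG tariff catalogue, a cohort Markov engine with a
    microsimulation oracle, and incident/prevalent-cohort budget projections
    under market-share scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
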