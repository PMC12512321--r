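Package: adaptsim
Title: Simulation of Two-Arm Adaptive Trials with an Event-Triggered
    Interim Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A modular simulation engine for two-arm, parallel-group
    adaptive clinical trials with a single event-triggered interim
    analysis. Provides building blocks for permuted-block randomisation,
    uniform participant accrual, binomial outcome generation, selection
    of the interim dataset once a pre-specified number of events has
    accrued, and closed-form Wald logistic-regression analysis of the
    2x2 treatment-by-outcome table with fixed alpha-spending decision
    thresholds. A Monte-Carlo engine with per-trial reproducible seeding
    aggregates simulated trials into operating characteristics (type I
    error, power, probability of early stopping, expected sample size,
    flip-flop probability) and six-number summary tables, and analytic
    two-proportion sample-size and odds-ratio calculations support
    design work. Defaults reproduce the design of the PIMS trial of
    intravenous fluid composition in children, whose binary primary
    outcome is hyponatraemia.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
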