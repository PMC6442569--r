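Package: bedbugsis
Title: Bed Bug Infestation Dynamics and Disclosure Policy Analysis in Rental Markets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coupled rental-market/bed-bug-infestation compartmental model
    (susceptible-infested-susceptible with vacancy dynamics) for evaluating
    infestation-disclosure policies. Provides closed-form endemic-equilibrium
    calibration of the infectivity to a target baseline prevalence, basic
    reproductive ratio analysis via the next-generation-matrix method with a
    route decomposition, deterministic time integration with event
    accumulators and landlord cost accounting (treatment, turnover, vacancy),
    break-even and discounting analyses, policy-surface sweeps over baseline
    prevalence and renter selectivity, one-at-a-time sensitivity analyses with
    recalibration, an open-population intermarket-migration variant, and an
    exact event-driven stochastic counterpart for validating the mean-field
    dynamics.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    lhs,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
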