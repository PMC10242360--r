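Package: rwcea
Title: Real-World Cost-Effectiveness Analysis with Inverse Probability Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for real-world cost-effectiveness analysis of two-arm
    observational cohorts with censored cost and survival data. Implements
    propensity-score inverse probability of treatment weighting (IPTW) with
    weighted standardized-difference balance diagnostics, a partitioned
    inverse-probability-of-censoring-weighted (IPCW) estimator of mean
    discounted costs and life-years on a 30-day grid, quality-adjusted
    life-year construction from progression-based health-state timelines
    with moment-matched beta utilities, bootstrap inference for incremental
    cost-effectiveness ratios with cost-effectiveness planes and
    acceptability curves, net-benefit regression, and discount-rate and
    drug-price sensitivity analyses. Includes a synthetic cohort and cost
    ledger generator with Monte-Carlo ground-truth estimands for validating
    the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
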