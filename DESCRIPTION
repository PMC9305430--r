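Package: fsanps
Title: FSA-NPS Basket Scoring, Future-Self Avatar Rules and Receipt-Based
    Trial Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scoring engine for the British Food Standards Agency Nutrient
    Profiling System (FSA-NPS, the basis of the Nutri-Score framework)
    applied to grocery products and digital loyalty-card receipts.
    Converts per-100 g nutrient profiles into component points and total
    scores, aggregates receipts into solid-food and beverage dietary
    indices, drives a five-feature future-self avatar state machine from
    recent step counts and basket history, ranks food categories by their
    contribution to negative points and proposes healthier in-category
    substitutes, simulates two-arm mobile-health trial cohorts with
    configurable effects and attrition, and reproduces the nonparametric
    trial analysis machinery (Wilcoxon signed-rank, Mann-Whitney U,
    Pearson chi-square, period aggregation, sensitivity analysis and
    sample-size calculation).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
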