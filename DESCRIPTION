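Package: produceRx
Title: Microsimulation Cost-Effectiveness Analysis of Produce Prescription Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level state-transition microsimulation of national
    produce prescription programs for adults with diabetes and food
    insecurity. Generates survey-weighted synthetic cohorts calibrated to
    published population marginals, pools study-level intervention effects by
    random-effects meta-analysis, simulates paired (policy versus status-quo)
    annual health-state transitions with common random numbers, accrues
    intervention, health-care, acute-event and productivity costs and EQ-5D
    utilities, and performs full cost-effectiveness analysis: incremental
    cost-effectiveness ratios, probabilistic sensitivity analysis with
    Rubin's-rule uncertainty intervals, cost-effectiveness acceptability
    curves, subgroup and one-way sensitivity analyses, and break-even cost
    threshold analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
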