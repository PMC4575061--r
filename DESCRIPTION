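Package: glaucomaCEA
Title: Cost-Effectiveness Modelling of Teleglaucoma Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic modelling of teleglaucoma screening versus
    in-person examination for glaucoma in rural populations. Implements a
    progressive five-state Markov cohort model (at-risk, mild, moderate,
    severe, blind) with discounted cost and QALY accumulation, a screening
    decision tree driven by prevalence and test sensitivity/specificity,
    incremental cost-effectiveness (ICER), dominance and net monetary
    benefit analysis, one-way deterministic sensitivity analysis and
    tornado ranking, second-order probabilistic sensitivity analysis with
    gamma/beta parameter distributions, and cost-effectiveness
    acceptability curves. Ships a calibrated reference parameter set, a
    YAML configuration format, a transition-probability calibration
    routine, and a random scenario generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
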