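Package: foscea
Title: Markov Cohort Cost-Effectiveness Analysis of Antiseizure Medications
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-state Markov cohort model for the economic evaluation of
    adjunctive third-generation antiseizure medications in pharmacoresistant
    focal-onset seizures, from a payer perspective. Provides the cohort trace
    engine over a 2-year horizon of 3-month cycles, state- and adverse-event
    based costing, year-two discounting, deterministic incremental
    cost-effectiveness analysis with dominance classification, and
    second-order Monte Carlo probabilistic sensitivity analysis with
    incremental cost-effectiveness plane summaries and cost-effectiveness
    acceptability curves. Includes beta and gamma moment-matching from
    reported means and standard errors, a synthetic model-instance generator,
    and an individual-level microsimulation oracle for validating the cohort
    expectation engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
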