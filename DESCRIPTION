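Package: filtercascade
Title: Filter-Cascade Cost-Effectiveness Models for Care Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic "filter" models for care pathways: a population
    is propagated through an ordered sequence of proportion filters (condition
    prevalence, setting attendance, detection, treatment reach, adherence,
    outcome), intervention unit costs are attached to steps, and intervention
    scenarios are compared with usual care via incremental cost, incremental
    successes, the incremental cost-effectiveness ratio (ICER) and a
    cost-effectiveness-plane classification. Supports deterministic
    sensitivity analysis via interval bounds on any input parameter, a
    config-file driven command-line interface, and an individual-level
    Bernoulli microsimulation used to validate the cohort-expectation
    arithmetic. Ships a worked example on depression management in Australian
    general practice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
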