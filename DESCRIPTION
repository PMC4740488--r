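Package: wakeupcea
Title: Cost-Effectiveness Micro-Simulation of MRI-Guided Thrombolysis for
    Wake-Up Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Micro-simulation model comparing an MRI-based (DWI-FLAIR
    mismatch) thrombolysis decision rule against no treatment for acute
    ischemic stroke patients whose onset occurred during sleep. Simulates
    true stroke-onset timing, the delay chain to treatment, a diagnostic
    rule with imperfect sensitivity and specificity, time-banded odds-ratio
    effects of tissue-type plasminogen activator on modified Rankin Scale
    outcomes, and a lifetime Markov model of discounted costs and
    quality-adjusted life years. Includes incremental cost-effectiveness
    statistics, one-way, two-way, threshold and probabilistic sensitivity
    analyses with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
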