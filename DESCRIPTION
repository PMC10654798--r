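Package: crcscreen
Title: Markov Cohort Cost-Effectiveness Model for Colorectal Cancer
    Screening with Liquid Biopsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort-level Markov state-transition model of colorectal
    cancer screening in average-risk US adults, comparing no screening,
    annual faecal immunochemical testing, decennial colonoscopy, triennial
    stool DNA, triennial blood-based liquid biopsy, and a colonoscopy/liquid
    biopsy hybrid. Includes a synthetic-epidemiology generator (life table,
    baseline cancer incidence, polyp prevalence, stage inputs), natural
    history calibration, per-strategy cost and life-year accrual with
    discounting, incremental cost-effectiveness frontier analysis with
    strict and extended dominance, one-way and threshold sensitivity
    analyses, scenario analyses, and probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
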