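Package: readmitbn
Title: Discrete Bayesian Networks for Unplanned Hospital Readmission
    Analysis in Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits multinomial Bayesian networks to small categorical
    clinical cohorts, with the workflow used to study unplanned hospital
    readmissions in gastrointestinal-cancer patients: clinical
    discretization of continuous measurements, pairwise Pearson chi-square
    association screening, knowledge-constrained (whitelist/blacklist)
    structure learning by BIC-scored hill climbing with an exhaustive
    oracle for small instances, maximum-likelihood and Laplace-smoothed
    conditional probability tables, exact posterior inference by variable
    elimination, Markov-blanket and d-separation graph diagnostics, and a
    calibrated synthetic-cohort generator so the whole pipeline runs
    without access to the original patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
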