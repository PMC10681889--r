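Package: hehrisk
Title: Cytogenetic Risk Profiling of High Hyperdiploid Acute Lymphoblastic Leukaemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses ISCN karyotype strings from clinical cytogenetics reports,
    applies high-hyperdiploidy (modal number 51-67) eligibility and exclusion
    rules, and classifies patients into good- and poor-risk groups from the
    trisomy status of chromosomes 5, 17, 18 and 20, with definite and
    provisional assignment when marker chromosomes or incomplete karyotypes
    leave the profile uncertain. Includes a synthetic-cohort simulator
    (karyotypes, covariates and exponential time-to-event endpoints under
    proportional hazards) and a survival validation layer: Kaplan-Meier
    estimates with log(-log) intervals, log-rank tests, Cox models with Efron
    tie handling, Harrell's concordance, Schoenfeld proportionality checks and
    subgroup forests with Cochran's Q heterogeneity tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    yaml,
    optparse
Config/testthat/edition: 3
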