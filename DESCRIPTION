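Package: signalmine
Title: Disproportionality Signal Mining for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance signal detection
    on FAERS-format quarterly extracts: reads the dollar-delimited DEMO, DRUG,
    REAC, THER and OUTC tables, deduplicates cases by case number keeping the
    most recent submission, selects a primary-suspect drug cohort, maps MedDRA
    preferred terms to system organ classes, builds report-level fourfold
    contingency tables, and computes four disproportionality statistics
    (reporting odds ratio, proportional reporting ratio with Pearson chi-square,
    the Bayesian confidence propagation neural network information component,
    and the empirical Bayes geometric mean in its relative-reporting-ratio
    form) with 95 percent intervals and combined signal criteria. Includes
    descriptive summaries (demographics, outcomes, time to onset), a synthetic
    FAERS corpus generator with planted drug-event association strengths for
    offline validation, and a contingency-table reconstruction tool for
    checking published signal tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
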