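Package: srsmine
Title: Descriptive Analysis and Disproportionality Signal Mining for
    Spontaneous Adverse Drug Reaction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance analysis of individual case
    safety reports from a spontaneous reporting system, oriented at
    antineoplastic-drug adverse reactions in pediatric patients. Provides
    report ingestion with inclusion/exclusion filtering and an audit trail,
    coding of reports (drug-name normalization, system-organ-class mapping,
    seriousness classification, analysis bins), severity-stratified
    descriptive tables with Pearson chi-square and Fisher exact tests,
    drug-event disproportionality statistics (reporting odds ratio,
    proportional reporting ratio, and the MHRA Yates-corrected chi-square
    criterion) with signal flagging, and a seeded synthetic report generator
    with injectable drug-event associations for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
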