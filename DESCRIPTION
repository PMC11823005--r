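Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Adverse
    Event Reports
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection in
    FDA Adverse Event Reporting System (FAERS) quarterly data: ingestion
    of the "$"-delimited ASCII tables across both the legacy (ISR-keyed)
    and current (primaryid-keyed) schemas, case-version deduplication,
    drug-name normalization and dictionary-based class assignment with
    primary-suspect filtering, MedDRA-style hierarchy handling with
    primary-SOC selection and HLT/HLGT-level adverse-event grouping,
    indication-stratified reporting odds ratio (ROR) disproportionality
    with Wald confidence intervals and signal criteria, descriptive
    tabulation, and time-to-onset analysis.  Ships a synthetic
    spontaneous-report generator with known ground truth (injected
    odds ratios, onset-time distributions, duplicate and missingness
    rates) so every pipeline stage is verifiable without access to the
    real database or a licensed MedDRA distribution.
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
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
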