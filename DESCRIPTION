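Package: lungdx
Type: Package
Title: Mutation and Gene Fusion Diagnostics for Non-Small Cell Lung Cancer Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted-panel precision diagnostics in non-small cell
    lung cancer: an RNA probe-count gene fusion caller for ALK, RET and ROS1
    (negative-control background correction, positive-control scaling,
    housekeeping QC failure detection, 3'/5' kinase-flank imbalance ratio and
    fusion-specific junction signal with quadrant classification), variant
    filtering and actionability annotation for a 26-gene amplicon panel,
    paired-call concordance evaluation against single-gene assays, cohort
    stratification by actionable driver alterations, and a seeded
    synthetic-data generator emulating the variant and hybridization batch
    structure of a one-year consecutive clinical testing cohort.
License: GPL-3
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
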