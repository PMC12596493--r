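Package: multimorbnet
Title: Sex- and Age-Stratified Multimorbidity Network Analysis of Inpatient ICD-10 Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multimorbidity networks from long-format inpatient
    admission records coded in ICD-10. Provides cohort ingestion and
    filtering (3-character category normalisation, Chapter 1-14 scope,
    baseline-record selection), descriptive multimorbidity profiles,
    pairwise disease association by exact logistic odds ratios with
    Bonferroni-corrected edge selection, three-level network
    decomposition (complete, sex-specific/sex-overlapped, sex-age),
    hub-disease identification with coverage statistics, ICD-10 chapter
    pattern-frequency ranking, and a synthetic cohort generator with
    planted pairwise odds ratios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
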