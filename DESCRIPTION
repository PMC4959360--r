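Package: srsanon
Title: Privacy-Preserving Anonymization of Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sanitizing spontaneous reporting system (SRS) adverse
    drug event tables before publication. Implements the MS(k, theta*)-bounding
    privacy model, in which every released QID-group must contain at least k
    distinct cases and the inferable probability of each protected sensitive
    value (with or without linkage to an external drug-disease knowledge table)
    must stay below a per-value threshold. Provides a two-stage greedy
    clustering anonymizer driven by an information-loss-times-privacy-risk
    metric, value generalization hierarchies for categorical quasi-identifiers,
    anonymization quality metrics (normalized information loss, dangerous
    ratio), pharmacovigilance disproportionality statistics (PRR, ROR, IC) with
    standard signal criteria, and a synthetic FAERS-like report generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tidyr,
    withr
Config/testthat/edition: 3
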