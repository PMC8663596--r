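Package: sbdhrisk
Title: Social and Behavioral Determinants of Health and Nonfatal Opioid
    Overdose Risk in ICU Admissions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for studying risk factors of nonfatal
    opioid overdose among intensive-care admissions when social and
    behavioral determinants of health (SBDH) are buried in free-text notes.
    Provides a synthetic MIMIC-like cohort generator with a known
    outcome-generating logistic model; a rule-based clinical note
    sectionizer; a lexicon-driven SBDH extractor with negation and
    temporality handling behind a pluggable labeler interface; ICD-9
    phenotype mapping for clinical variables, structured SBDH and the
    overdose outcome; integration with structured-"yes" precedence; and a
    statistical layer with crude odds ratios, multivariable logistic
    regression fit by iteratively reweighted least squares, sequential
    forward selection, Hosmer-Lemeshow goodness of fit, and variance
    inflation factors.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
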