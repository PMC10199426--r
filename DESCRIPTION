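Package: neutrality
Title: Neutrality Scoring of Clinical Study Endpoints Against Disease-Severity Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores how well the endpoint set of a clinical study matches a
    disease-specific disease-severity scale used as a surrogate for the disease
    phenotype. Endpoints are classified into overlapping, redundant, missing and
    irrelevant indicators; sensitivity, specificity and their sum (the
    Neutrality score, 2 = perfect, > 1.50 acceptable) are computed per study and
    aggregated per disease, including comparisons of the first published scale
    against a composite of later scales. The mismatch is propagated into
    prevalence-dependent positive/negative predictive values and false
    positive/negative classification risk, analytically and by seeded Monte
    Carlo simulation over trial-sized cohorts. Includes a synthetic-data
    generator with controlled overlap structure and curated reference tables
    from a published systematic review of rare-disease severity scales.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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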