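Package: injurywatch
Title: Media-Report Surveillance of Product-Related Child Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale infoveillance toolkit for product-related child
    injury reported in online news and social-media stories. Provides a
    synthetic story generator with embedded ground truth, keyword-dictionary
    candidate search, rule-based eligibility filtering and near-duplicate
    suppression, a pluggable eligible-story classifier with a
    support-weighted metric suite, rule-based extraction of 34 structured
    fields (regular expressions, gazetteer entity matching, and
    keyword-plus-relation patterns), extraction scoring against gold
    records, surveillance analytics (administrative-geography coverage,
    keyword frequencies, trend series, early-signal detection with lead
    times), and a file-backed store with batch pipeline orchestration and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
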