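Package: langscreen
Title: Adaptive Milestone-Based Screening for Early Language Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for milestone-based screening of language development in
    children aged 1 to 36 months. Provides a month-question-suggestion
    knowledge-base model with validation, JSON serialization and graph
    (Cypher-style) export; an age-adaptive screening engine that selects
    questions, applies warning/alarm decision rules and produces graded
    suggestions (typical development, repeat in 1-3 months, or refer to early
    intervention); a synthetic knowledge-base and cohort simulator with a
    latent-ability answer model; evaluation statistics (latest-per-child
    filtering, suggestion distributions, stratified alarm rates, evaluator
    concordance, finite-population sample-size calculation); and packaged
    field-study summary tables with a deterministic record reconstructor for
    end-to-end testing without any real child data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
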