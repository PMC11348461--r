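Package: qsargep
Title: Two-Stage QSAR Modeling with Heuristic Forward Selection and Gene
    Expression Programming
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-stage quantitative structure-activity
    relationship (QSAR) modeling of RANKL/RANK inhibitor activity:
    descriptor pre-screening (degenerate, inter-correlated and
    low-relevance columns), heuristic forward-selection multiple linear
    regression with leave-one-out cross-validated R2 and the
    breaking-point model-size rule, and a gene-expression-programming
    symbolic-regression engine over Karva-encoded {+,-,*,/} expression
    trees.  Ships a transcription of the study's 39-compound TRAP
    inhibition table with a typographic audit trail, model-quality
    statistics for train/test comparison of the linear and evolved
    models, and a synthetic descriptor-table generator with planted
    linear or expression responses for parameter- and
    expression-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
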