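Package: metacogsdt
Title: Metacognitive Sensitivity Analysis for Confidence-Rating Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating metacognitive sensitivity from
    confidence-rating two-alternative forced-choice data. Implements
    type-1 signal detection estimation (equal-variance d' and
    unequal-variance da with zROC slope), maximum-likelihood meta-d'
    and meta-da fitting, and the M-ratio measure of metacognitive
    efficiency. Includes a synthetic-observer module that simulates
    perceptual (1-up/2-down contrast staircase) and recognition-memory
    sessions for whole two-group cohorts, plus the group-level
    statistical pipeline (Levene-guided t-tests, mixed Group x Task
    ANOVA, Pearson correlations) used to compare metacognition between
    groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
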