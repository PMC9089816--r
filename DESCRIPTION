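Package: cfaopt
Title: Accuracy-Cost Optimisation of Cognitive and Functional Assessment Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-sensitive selection of cognitive and functional assessment
    (CFA) items for staging dementia severity (CN/MCI/AD). Implements the
    correlation-based feature selection (CFS) merit heuristic with a
    lambda-weighted administration-time penalty and forward best-first search,
    companion selectors (consistency-based selection and a Boruta-style
    shadow-feature random-forest wrapper), Hand-Till multiclass AUC under
    feature-selection-aware and standard stratified cross-validation, a
    lambda sweep with Pareto-front extraction of the accuracy-vs-time
    trade-off, and a synthetic assessment-data generator with known
    ground-truth item roles for end-to-end testing. Includes a command-line
    interface for simulation, selection, evaluation and the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
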