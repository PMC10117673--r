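Package: oncoTargetML
Title: Therapeutic Target Prioritisation from Protein Embeddings and Omics Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assembles balanced target/non-target gene datasets for individual
    cancer types, builds integrated per-gene feature vectors (1,024-dimensional
    protein sequence embeddings plus five omics summary features), trains a
    compact deep neural network classifier alongside random-forest, gradient
    boosting and SVM baselines, and evaluates models with stratified k-fold
    cross-validation, a disjoint-negative-set protocol and a Y-randomization
    (label permutation) test. Unlabeled genes are ranked by predicted target
    probability to nominate novel therapeutic targets. A seeded synthetic data
    generator emulates every input (protein sequences, expression matrices,
    mutation tables, embedding clouds with controllable class separation) so
    the full pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings,
    randomForest,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
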