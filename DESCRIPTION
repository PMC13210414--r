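Package: painconn
Title: Connectivity-Based Subject-Independent Pain Recognition from fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a subject-independent three-class pain-recognition
    pipeline for multichannel fNIRS haemodynamic signals: synthetic cohort
    generation with planted class-dependent connectivity, channel quality
    control and five-step signal conditioning, four connectivity estimators
    (Pearson correlation, partial correlation, magnitude-squared coherence,
    pairwise Granger causality) vectorised into a canonical named feature
    space, mutual-information feature ranking under leave-one-subject-out
    cross-validation, a feature-count sweep with parsimony-based model
    selection, and feature-stability reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    class,
    e1071,
    randomForest,
    xgboost,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
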