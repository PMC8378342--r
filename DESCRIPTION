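Package: esdm
Title: Ensemble Species Distribution Modelling with Climate-Scenario Range Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits metric-gated weighted-average ensemble species distribution
    models from presence-only records and gridded marine environmental layers.
    Covers the full workflow: occurrence thinning and extent filtering,
    pseudo-absence sampling in contrasting environmental conditions via a
    surface range envelope, a ten-algorithm learner zoo under repeated
    stratified cross-validation, retention gating on the true skill statistic
    and AUC, TSS-proportional ensemble weighting, TSS-maximising binarization,
    permutation variable importance, response curves, and range-change
    projection under additive climate-scenario shifts. Includes a
    virtual-species generator so every stage is testable without external
    data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    nnet,
    rpart,
    randomForest,
    xgboost,
    glmnet,
    MASS,
    splines,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
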