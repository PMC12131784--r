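Package: mbssm
Title: Multi-Body Statistical Shape Models for Corresponded Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of single-body and combined multi-body
    statistical shape models (point distribution models) from corresponded 3D
    point clouds. Builds PCA shape models over concatenated shape vectors,
    fits and regularizes model parameters inside the Mahalanobis plausibility
    ellipsoid, and provides the standard validation battery (leave-one-out
    ground-truth accuracy, generalization by training-set size and by number
    of components, specificity, compactness). Quantifies coupled variation
    between two bodies by decomposing combined-model eigenvectors into
    single-body modes, predicts a missing counterpart body from its partner
    via regression on block-decomposed model coefficients, and assesses bias
    of de novo synthetic-population generation through chi-squared
    plausibility and Kolmogorov-Smirnov uniformity testing. Includes a
    seeded generator of paired synthetic cohorts with a controllable
    coupled-variation fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
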