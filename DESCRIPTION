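Package: wddscreen
Title: Weighted Diversity Density Models for Interpretable Clinical Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits weighted diversity density (WDD) classifiers for binary
    screening on tabular clinical data with missing values. Three variants are
    provided: an imputation-based model (KNN), a division-penalty
    missing-value-tolerant model (DI), and a bounded-similarity model that
    ignores missing features (BF). The package covers the full screening
    pipeline: robust normalization with IQR outlier nulling, k-nearest-neighbour
    imputation, class-balanced missingness equalization, gradient-based fitting
    of a prototype point and nonnegative feature weights, Youden-index decision
    thresholds, repeated stratified cross-validation with a fixed independent
    test split, per-feature risk decompositions and weight-based feature
    importance, and age/sex subgroup modelling. A seeded synthetic cohort
    generator with class-conditional Gaussian marginals supports end-to-end
    testing without access to clinical records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
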