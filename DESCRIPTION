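Package: lungfractal
Title: Morphometric Complexity Biomarkers of Lung CT for Radiation
    Pneumonitis Risk Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three-dimensional morphometric complexity biomarkers
    (box-counting fractal dimension, gliding-box lacunarity, and minimum
    spanning tree fractal dimension) from Hounsfield-unit thresholded lung
    CT masks, derives dose-volume histogram predictors, compares paired
    pre- and post-radiotherapy measurements with exact Wilcoxon signed-rank
    tests, and fits an interpretable radiation pneumonitis risk model
    (random-forest feature ranking followed by a cost-complexity pruned
    decision tree tested against the no-information rate). A synthetic-data
    module generates fractal phantoms of known dimension and cohorts with
    planted decision rules so that every stage is verifiable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    randomForest,
    rpart,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
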