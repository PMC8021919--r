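Package: brainagekit
Title: Hierarchical Brain-Age Prediction from Structural MRI Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, config-driven pipeline for brain-age prediction
    from multichannel structural brain volumes. Generates age-structured
    synthetic brain phantoms, extracts parcel-wise and spatial-ICA features,
    fits ridge and RBF-kernel support-vector baselines under nested 10-fold
    cross-validation, trains a 26-layer 3D residual convolutional age
    regressor with covariance and ranking-relationship regularization
    losses, ensembles model predictions by median aggregation with a
    bias-aware checkpoint-selection rule, and evaluates predictions with
    MAE, RMSE, R-squared, Kullback-Leibler divergence of the age
    distributions, and Spearman correlation of the brain-age delta,
    including chronological-age bias correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
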