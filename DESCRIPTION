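Package: cloudclass
Title: Multiscale Geometric Classification of 3D Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Supervised semantic classification of 3D point clouds from
    laser scanning or photogrammetry using only point coordinates. Per-point
    shape descriptors (linearity, planarity, sphericity, horizontality and a
    robust vertical extent) are computed from the eigendecomposition of the
    local covariance matrix inside spheres of several diameters, and the
    resulting multiscale feature table is fed to one of four multiclass
    models (linear discriminant analysis, multinomial logistic regression,
    RBF support vector machine, random forest). Includes one-vs-all
    evaluation metrics (precision, recall, F1, overall accuracy, Cohen's
    kappa), Gini-based variable importance, synthetic labeled urban and
    forest scene generators for end-to-end testing, and a command-line
    pipeline.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    nnet,
    e1071,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
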