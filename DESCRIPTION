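Package: hepanode
Title: Characterization of Small Hypoattenuating Hepatic Nodules with a
    Convolutional Network and Clinical Covariate Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, training and evaluation pipeline for classifying
    small (<10 mm) hypoattenuating hepatic nodules on contrast CT as benign
    or malignant. Provides a synthetic patch-cohort generator with ground
    truth masks and a synchronous liver-metastasis covariate, dihedral
    crop-translation data augmentation with class-balanced oversampling, a
    small convolutional network trained under patient-grouped 5-fold
    cross-validation with per-lesion probability aggregation, logistic
    fusion of network probability with liver-metastasis status, a
    nonparametric diagnostic-performance stack (Mann-Whitney AUC, DeLong
    paired AUC comparison, unweighted kappa, McNemar, ordinal confidence
    conversions), and interpretability tools (region features, k-means
    probability clusters, penultimate-layer t-SNE embeddings).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    jsonlite,
    pracma,
    Rtsne,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
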