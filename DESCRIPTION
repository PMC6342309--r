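Package: heqct
Title: Homology-Based Emphysema Quantification and Lung Cancer Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies pulmonary emphysema on chest CT by two routes: the
    classical low-attenuation area percentage (LAA%) and a topological
    descriptor built from the Betti numbers (b0, b1) of the binarized
    low-attenuation lung set at fixed Hounsfield-unit thresholds. Provides
    slice selection, thresholding, exact cubical-homology invariants for
    2-D binary images, logistic risk models adjusting for age, sex and
    smoking history, ROC/AUC analysis with DeLong comparison of correlated
    AUCs, stratified k-fold cross-validation, and fully synthetic phantom
    and cohort generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    EBImage,
    png,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
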