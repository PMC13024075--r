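Package: volpct
Title: Population-Referenced Brain Volumetric Percentiles for Dementia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits per-region age- and sex-adjusted normative regression models
    of regional brain volumes on a cognitively normal reference cohort,
    converts individual regional volumes into population-referenced
    percentile scores, and trains a class-weighted, ridge-penalized logistic
    classifier separating Alzheimer's disease from cognitively normal
    subjects on the 95-region percentile profile. Includes a synthetic
    cohort generator emulating the assumed generative model, a stratified
    split and cross-validation protocol with train-set-only feature
    standardization, confusion-matrix metrics, ROC/AUC, validation-gap
    statistics, coefficient ranking, and an end-to-end experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
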