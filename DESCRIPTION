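Package: hescreen
Title: Weakly Supervised Prediction of Immune-Checkpoint Status from H&E
    Tissue-Microarray Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, desk-scale pipeline for predicting patient-level
    PD-L1/PD-1 status from H&E-stained tissue-microarray (TMA) core images
    under patient-level weak labels: cohort assembly with exclusion
    accounting, leak-free patient-level splits and cross-validation folds,
    deterministic inference cropping and stochastic training augmentation, a
    compact residual convolutional network trained with focal loss and the
    RAdam optimizer, max-over-core aggregation to patient scores, last-layer
    calibration to external cohorts, a decision-support statistics layer
    (NPV/sensitivity/specificity triage, Cohen's kappa, ROC AUC with
    bootstrap confidence intervals, screening curves), and 2-D embedding of
    the learned feature space.  A synthetic TMA cohort generator with a
    planted, label-correlated morphological signal makes every stage
    testable end to end, with an analytic oracle for the best achievable
    AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    png,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
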