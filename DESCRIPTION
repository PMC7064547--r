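Package: gglearn
Title: Learning-Curve Analysis of Goalkeeper Game Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a constrained Bernoulli learning-curve model to
    trial-level success sequences from the Goalkeeper Game, a
    three-stage penalty-prediction task used to profile procedural
    learning in Parkinson's disease. Per patient and stage the model
    estimates a learning rate (beta) and an asymptotic success
    probability (gamma) by Bayesian quadrature; together with mean
    response times these form a nine-variable performance profile.
    The package quantifies association between the profile and an
    ordinal gait score (Dynamic Gait Index) via polyserial and
    polychoric correlations and a proportional-odds model, and
    compares the profile against a global cognitive score (MoCA) as
    cross-validated elastic-net predictors of dichotomized gait
    performance, with exact binomial tests, ROC/AUC and DeLong paired
    AUC comparison. A synthetic-cohort generator with known ground
    truth supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mvtnorm,
    jsonlite,
    withr
Config/testthat/edition: 3
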