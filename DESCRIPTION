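Package: spastimas
Title: Quantitative Spasticity Assessment from Instrumented Passive Elbow Stretches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for grading upper-limb spasticity on the
    Modified Ashworth Scale (MAS) from multi-channel passive elbow-stretch
    recordings (twin-axis goniometer angles, myometer resisting force, surface
    EMG). Covers signal conditioning (median/mean filtering, zero levelling,
    rectified low-pass EMG envelopes), automatic stretch segmentation from
    angle extrema, catch (maximum-deceleration) detection, extraction of 17
    kinematic, kinetic and physiological stretch features, imbalanced-dataset
    preparation (stratified splitting, standard scaling, random oversampling
    and SMOTE), five baseline classifiers with tuned hyperparameters, a
    rule-based Logical-SVM-RF classifier cascade for the six MAS grades, a
    multiclass evaluation suite with confusion-count reconstruction from
    rounded published metrics, and a MAS-conditioned synthetic stretch-session
    generator with planted ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    randomForest,
    rpart,
    signal,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
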