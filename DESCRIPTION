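Package: endoskill
Title: Multimodal Evaluation of Endoscopic Training Skill
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator-independent evaluation of endoscopic (2D versus
    stereoscopic 3D) training from multimodal recordings: a seeded
    synthetic-cohort generator for 8-channel surface EMG, armband
    orientation and 8-joint skeleton streams; sync-gesture based attempt
    segmentation with a 90-second abort rule; per-attempt spectral,
    amplitude and morphology sEMG features plus kinematic motion-analysis
    parameters (160 canonical metrics); repeated-measures ANOVA over
    attempt sessions with Huynh-Feldt epsilon correction; median
    Euclidean and Mahalanobis distance maps between 2D and 3D
    metric-specific vectors with affiliation-averaged heatmaps; and
    distance-based feature selection with cross-validated endoscope-type
    classification over a roster of SVM, k-NN, tree and ensemble
    learners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tibble,
    dplyr,
    jsonlite,
    withr,
    MASS,
    e1071,
    rpart,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
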