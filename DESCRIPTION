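Package: fohtelem
Title: Predicting Daily Feeling-of-Health from Telemonitoring Data in Heart Failure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for predicting daily self-reported
    feeling-of-health (FOH) in congestive-heart-failure patients from
    wearable and ambient telemonitoring streams. Includes a synthetic
    cohort generator with persistent latent health states and two
    label dialects (day-over-day vs. relative-to-usual), rule-based
    label-schema harmonization, windowed feature extraction with
    personal ratios, global and personalized missing-data imputation
    (KNN and chained equations), SMOTE class rebalancing, random-forest
    classification, and three cross-validation protocols (10-fold,
    leave-one-subject-out, leave-half-a-subject-out) with accuracy and
    macro-F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
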