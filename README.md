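# fohtelem

Predicting daily **feeling of health (FOH)** in congestive-heart-failure
patients from telemonitoring data.

Patients with CHF report how they feel each day on a 5-point scale, while
wearables, cuffs, scales and ambient sensors record their physiology and
environment. `fohtelem` implements a complete, tested analysis pipeline for
predicting the daily FOH class from those streams, built around the
questions that matter for deployment: *do such models generalize to unseen
patients, or do they need personalization — in the model, in the
evaluation protocol, and in the missing-data handling?*

The pipeline covers:

* **Synthetic cohort generation** — per-patient physiological baselines, a
  sticky latent daily health state (3-state Markov chain, stationary
  distribution = its redraw distribution), two FOH label dialects
  ("relative to yesterday" vs. "relative to usual"), structured MCAR
  missingness (per-channel day dropout + multi-day non-wear blocks), and
  full ground truth for recovery tests.
* **Label harmonization** — 5→3 class merging with dialect-aware scale
  direction, and the rule-based rewriting of yesterday-relative labels
  into usual-relative ones (propagation over runs of 'same' days capped at
  five days, opposite-pair smoothing, no assumptions across reporting
  gaps).
* **Feature extraction** — registry-driven, per-FOH-day feature vectors
  for both dialects: windowed means/SDs (3 h, 24 h, day, week,
  day-over-day differences with fallback windows), rate-pressure product
  (SBP × heart rate near the measurement), double product, activity
  fractions and per-activity statistics, exercise logs, environmental
  statistics, and *personal ratios* (a value divided by the patient's own
  study-period aggregate).
* **Preprocessing** — missingness-threshold feature filtering, KNN and
  chained-equations (MICE-style) imputation in **global** vs.
  **personalized** scope, and an optional previous-day-FOH feature.
* **Modeling** — SMOTE oversampling applied to training folds only, a
  default-parameter random forest, impurity feature importances, and
  cross-dataset training on the name-intersected compatible feature set.
* **Evaluation** — 10-fold CV, leave-one-subject-out (LOSO), and
  leave-half-a-subject-out (per-patient temporal split); accuracy and
  per-class/macro F1; Welch t-tests on fold scores; leakage guards
  throughout.

The macro F1 over classes c with per-class precision P_c and recall R_c is

    F1_c = 2 · P_c · R_c / (P_c + R_c),   macro F1 = mean_c F1_c

and is the canonical metric here: the 'same' class dominates daily
self-reports, so accuracy mostly measures majority-class behaviour.

## Worked example

```r
library(fohtelem)

# a heterogeneous cohort: each patient's feature-FOH link has its own
# direction and strength, so population models should struggle
cfg <- sim_config(n_patients = 8, n_days = 50, dialect = "heartman",
                  effect_size = 2, effect_heterogeneity = 1,
                  missing_rate_channel = 0.15, report_prob = 0.85,
                  seed = 501)
cohort <- generate_cohort(cfg)
m <- build_feature_matrix(cohort)          # curate + extract + filter

for (sch in c("kfold10", "leave_half", "loso")) {
  print(evaluate_matrix(m, sch, imputation_plan("knn", "global"),
                        n_classes = 3, seed = 501))
}
```

Output from this exact script:

```
FOH evaluation (kfold10, 3 classes, global knn imputation)
  splits: 10   accuracy: 0.900   macro F1: 0.881 (SD 0.031)
FOH evaluation (leave_half, 3 classes, global knn imputation)
  splits: 1   accuracy: 0.763   macro F1: 0.704
FOH evaluation (loso, 3 classes, global knn imputation)
  splits: 8   accuracy: 0.617   macro F1: 0.432 (SD 0.245)
```

The ordering is the study's central qualitative finding: pooled 10-fold CV
(patient's own days on both sides of the split) looks excellent,
leave-half-a-subject-out (model has seen the patient's first weeks) stays
strong, and LOSO (never seen the patient) collapses toward chance — the
feature-FOH link is real but patient-specific, so prediction needs
personalization. `summary()` on any result adds per-split metrics and the
pooled confusion matrix; `feature_importance(fit_classifier(...))` ranks
features by normalized impurity importance.

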