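---
title: "Predicting daily feeling-of-health from telemonitoring data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting daily feeling-of-health from telemonitoring data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fohtelem)
```

## The problem

Congestive heart failure (CHF) is incurable; maintaining the patient's
health-related quality of life is a central treatment objective. Daily
telemonitoring (chest straps, wristbands, blood-pressure cuffs, scales,
ambient sensors) produces streams of physiological and environmental
measurements, and patients can self-report a daily *feeling of health* (FOH)
on a 5-point scale. `fohtelem` implements a complete, tested pipeline for
predicting the daily FOH class from such streams: label-schema
harmonization, windowed feature extraction, missing-data imputation,
class-rebalanced random-forest classification, and evaluation protocols that
distinguish population-level from personalized performance.

Real CHF telemonitoring datasets of this kind are not publicly deposited, so
the package ships a synthetic cohort generator that reproduces their
*statistical structure* — and, crucially, the ground truth needed to test
every stage against known answers.

## The synthetic cohort generator

Each patient carries a latent daily health state in
{worse, same, better} relative to their own usual condition. The state
follows a sticky Markov chain: day 1 is drawn from a marginal distribution
`state_probs`; each later day repeats the previous state with probability
`state_persistence` and is otherwise redrawn from `state_probs`. Because
non-persistent days redraw from the marginal, `state_probs` is exactly the
chain's stationary distribution — a property the tests exploit. The default
persistence of 0.8 encodes the observed pattern that patients feel bad for
a few days in a row; the default marginal (0.2, 0.6, 0.2) makes 'same' the
majority class at roughly the proportion seen in daily self-report studies.

Channel values are generated as

    value(t) = baseline_p + effect * m_p * sign(state_day) + noise(t)

where `baseline_p` is a per-patient draw (between-patient SD), `noise` is
within-patient variation, `effect` is a per-channel shift in channel units
(scaled globally by `effect_size`; heart rate rises on worse days, energy
expenditure and SpO2 fall, ambient channels do not respond), and `m_p` is a
per-patient effect coefficient. With `effect_heterogeneity = 0` every
patient shares the same feature-FOH link (`m_p = 1`); with
`effect_heterogeneity = 1`, `m_p ~ N(0, 1.5)`, so the link's direction and
strength become patient-specific and its population mean vanishes. The
second regime is how we emulate cohorts in which population models
(leave-one-subject-out) collapse while personalized models do not.

Default channel parameters (means, SDs, sampling frequencies) are plausible
values for an elderly CHF cohort: resting heart rate 72 ± 8 bpm between
patients, skin temperature 33 °C, SBP 125 mmHg, and so on. The source
studies never published their channel distributions, so these are free
choices; no claim of distributional match to any real cohort is made, and
none of the package's tests depend on the specific values.

Two label dialects are emitted. The *usual-relative* (HeartMan-style)
dialect reports the latent state directly on a 5-point scale whose low end
means "much better than usual". The *yesterday-relative* (Chiron-style)
dialect reports the ordinal change of the latent state versus the previous
calendar day, on a scale whose low end means "much worse than yesterday";
the first report after any reporting gap is "same", since the patient
cannot compare against an unreported yesterday. Both dialects split the
merged extremes uniformly over the two extreme answers (1/2 or 4/5) for
realism.

Missingness is MCAR and structured: per-channel day-level Bernoulli dropout
(a whole day of a channel disappears), plus contiguous multi-day non-wear
blocks that silence every wearable channel while manual entries and ambient
sensors continue. Every removed value is recorded in the ground truth, so
imputation can be scored against the truth. Informative (state-dependent)
missingness is deliberately out of scope: the source studies describe no
missingness mechanism, and MCAR keeps the recovery experiments
interpretable.

What the generator does **not** emulate: circadian or seasonal structure,
raw ECG/accelerometry waveforms, dropout correlated with health state, and
real-world data-entry pathologies beyond simple out-of-range values.
Passing tests therefore demonstrate that the pipeline's machinery is
correct under the stated assumptions — not that any particular accuracy is
attainable on real patients.

## Label harmonization

Both dialects use 5-point scales with opposite directions;
`merge_five_to_three()` collapses 1/2 and 4/5 and absorbs the direction, so
downstream code sees only {worse, same, better}.

`transform_yesterday_to_usual()` rewrites yesterday-relative labels as
usual-relative ones using a small rule set applied only within runs of
consecutive reporting days:

1. by default worse/same/better map to themselves;
2. a 'worse' followed by 'same' days propagates 'worse' over at most five
   consecutive days, the triggering day counting as day 1;
3. consecutive 'worse' days all stay 'worse';
4. a 'worse' immediately followed by 'better' turns that second day into
   'same';
5. nothing propagates across reporting gaps;
6. rules 2–4 apply symmetrically to 'better'.

The printed rules leave precedence open in corner cases; this implementation
scans left to right, checks the opposite-pair rule (4) before starting
propagation, halts propagation at any non-'same' label or at the 5-day cap,
and lets a later trigger restart its own window. A day rewritten to 'same'
by rule 4 is *consumed*: it neither anchors a new opposite pair nor
propagates. These choices are the minimal-assumption reading of the rules;
the test suite pins them down with an exhaustive comparison against an
independently written declarative oracle over every label sequence of
length ≤ 6.

The transformation is applied to 3-class canonical labels (the rules are
phrased in worse/same/better language); a 5-class-first variant is not
implemented. Transformation genuinely improves agreement with the latent
usual-relative state on synthetic cohorts, but not unboundedly: a 'worse'
label produced by a better→same latent transition with no preceding
consecutive 'better' report is indistinguishable from true worsening under
the rules as printed, which caps the attainable recovery.

## Feature extraction

Extraction is registry-driven: `feature_registry(dialect)` enumerates every
column with its source channel(s), window, statistic, and personal-ratio
flag, and the extractors emit exactly those columns, so the cross-dialect
compatible feature set is computable by name
(`<group>.<descriptor>.<window>.<stat>[.pratio]`).

The HeartMan-style dialect computes windowed statistics of the continuous
channels (3 h and 24 h before the FOH entry, the calendar day of the entry,
and day-over-day differences), skin/air-temperature and GSR/humidity
ratios, the rate-pressure product (SBP × mean heart rate within ±10 min of
the SBP event; no 3-hour variant, since blood pressure is measured about
once a day), weight/SBP/DBP deltas at lags 1 and 4 days, activity-class
fractions over day/24 h/week/difference windows, the static/dynamic
heart-rate ratio, exercise counts and durations (day and week), and ambient
statistics (day and 3 h). The Chiron-style dialect computes day-level and
per-activity (lying/sitting/moving) statistics, daily manual values, and
derived daily features: temperature and humidity ratios, RPP, the double
product (mean of SBP and DBP times heart rate), the SBP/DBP ratio,
activity-duration ratios, pairwise heart-rate differences and ratios across
activities, and the heart-rate/energy-expenditure mean sample ratio.

Numerical decisions, made once and documented here:

* **Window anchoring.** The 3 h/24 h/week windows end at the FOH entry
  timestamp (a fixed entry minute, default 20:00); "day of entry" is the
  calendar day 00:00–23:59. No feature may use measurements after the
  entry's calendar day.
* **Curation bounds are inclusive**: SBP above 200 mmHg, DBP below
  40 mmHg and heart rate below 40 bpm are removed; a value exactly at the
  limit is kept.
* **SD over fewer than two samples is missing**, never zero.
* **Delta fallbacks**: the 1-day difference falls back to the most recent
  value within 3 days (applied to all difference features, since the rule
  is stated generically); the 4-day delta falls back to the most recent
  value 5–7 days back.
* **Ratio channels** (skin/air temperature, GSR/humidity) are ratios of
  window means and are emitted as mean-only: an SD of a ratio of two
  unaligned streams has no clean definition.
* **Personal ratios** divide a mean-type feature by the patient's
  study-period mean of that column, and an SD-type feature by the patient's
  SD of that column; zero or undefined denominators yield missing. All
  feature groups except exercise get personal-ratio variants in the
  HeartMan dialect; the Chiron dialect personalizes its stated subset
  (temperature/humidity ratios, skin temperature, body humidity, QT, QRS,
  heart rate/energy).
* The exercise *validity* flag is a pass-through binary channel (its
  clinical definition is not public); ECG fiducials are represented by QT
  interval and QRS duration. The registry documents this implementation's
  enumeration and makes no claim of column-count parity with any study.

Every registered feature is tested for exact (1e-9) agreement with an
independent brute-force recomputation from the raw streams.

## Preprocessing

Features whose missing fraction *strictly exceeds* a threshold are dropped
("more than 30 %" / "more than 60 %" style; 0.3 is the Chiron-style
default, 0.6 the HeartMan-style default). Two imputers are provided, each
in *global* (one imputer on all fitting rows) and *personalized* (one
imputer per patient, global-mean fallback for patient-columns with no
observed value) scope:

* **KNN** (`k_neighbors = 5` by default): nan-Euclidean distances on
  features standardized by the fitting rows' means/SDs (distances must be
  comparable across channels with wildly different units), imputed value =
  mean of the k nearest donors observed in that column.
* **Chained equations** (`max_iter = 10`): mean initialization, then a
  ridge linear model per feature refit over the iterations — the classic
  MICE/IterativeImputer scheme in single-completion form. Multiple-draw
  pooling is out of scope.

The method names come from the source analysis; k = 5 and 10 iterations are
this package's defaults, since no parameters were published. Within
evaluation, imputers are **fitted on training rows only** and applied to
test rows. Whether the original analysis refit imputers per fold is
unstated; fitting per fold is the strict choice, and the leakage tests
byte-compare fitted state to prove test rows contribute nothing.

The optional previous-day FOH feature is yesterday's canonical class when
the previous calendar day has a report and 'same' otherwise (including a
patient's first-ever report); it is one-hot encoded so it can sit alongside
numeric features without being imputed (by construction it is never
missing).

When does personalized imputation actually help? Only when the patient's
own rows are not already the imputer's nearest neighbours. On
day-level value matrices with between-patient SD ≫ within-patient SD,
global KNN sometimes borrows a wrong patient's values and personalized KNN
cannot, which yields the tested recovery ordering (personalized RMSE <
global RMSE when between-SD = 3 × within-SD; parity when between-SD = 0).
On heavily derived feature matrices (personal ratios, differences) much of
the patient offset is already normalized away and the two scopes converge
— one plausible reading of why the original studies saw the benefit on one
dataset and not the other.

## Modeling

Training folds are rebalanced with SMOTE: each minority class is upsampled
to the majority count by interpolating between a class member and one of
its k = 5 nearest same-class neighbours (neighbourhood shrunk for classes
of size ≤ 5; a singleton class cannot seed neighbours and is left alone
with a warning). Oversampling is applied to training data only; synthetic
rows are flagged so the tests can prove none reaches a test partition.

The classifier is a random forest with its implementation defaults
(500 trees, `mtry = floor(sqrt(p))`), classes treated as unordered
categories. Feature importances are the forest's impurity (Gini)
importances, normalized to sum to 1. A single master seed fans out to
stage-specific seeds (splits, SMOTE, forest), so a full experiment grid is
reproducible end to end.

## Evaluation

Three split schemes:

* **kfold10** — random unstratified 10-way row partition (the easiest
  setting: a patient's days appear on both sides);
* **loso** — leave-one-subject-out, the previously-unseen-patient setting;
* **leave_half** — per patient, rows dated up to the midpoint of that
  patient's observed date span train, the rest test (ties to training:
  days 0–50 of a 0–100 span train). Patients with fewer than two rows are
  excluded and logged.

Metrics are accuracy (correct / total) and per-class one-vs-rest F1 with
the **macro** (equal-weight) average as the canonical aggregate — the
middle class dominates these datasets, and macro F1 is the summary that
does not reward majority-class behaviour. A support-weighted F1 is also
reported for reference. Fold-level scores are compared with an unpaired
Welch t-test (matching a mean ± SD presentation of fold scores; whether
the original comparison was paired is unstated).

Two-class experiments drop the 'same' rows *before* splitting. ROC
analysis is deliberately absent: the pipeline mixes binary and 3-class
outcomes, and a single threshold-free summary would not be comparable
across them.

### A subtlety in the negative control

With `effect_size = 0` the features carry no information about the labels —
but pooled schemes still beat naive permutation chance. The reason is not
leakage: daily labels are persistent, so per-patient label *marginals*
differ, and any model that can recognize a patient from their baselines
(which 10-fold CV and leave-half permit) can exploit that patient's
marginal without using any sensor-state signal. The correct chance level
therefore conditions on the marginals: the negative-control test permutes
truth labels *within patient* within each split and requires the observed
macro F1 to sit within 3 Monte-Carlo SDs of that null. This is also a
useful caution for interpreting pooled-CV results on real data.

## Problem sizes and runtime

The test suite runs the full pipeline at deliberately modest scales chosen
as representative rather than exhaustive: exhaustive rule-oracle checks
over all 3^6 label sequences; 20 × 120-day label cohorts for
transformation recovery; 5 × 30-day cohorts for the brute-force feature
oracle; 8 × 30-day cohorts for imputation recovery; 8 × 50-day cohorts
(10 seeds) for the leave-half vs. LOSO personalization gap; and an
8 × 40-day zero-signal cohort for the negative control. The complete suite
runs in a few minutes on one CPU.

## Known limitations

* MCAR missingness only; real non-wear is plausibly state-dependent.
* The latent state is 3-valued; 5-point raw answers are a presentation
  layer, not a finer latent scale.
* Single-site semantics: calendar dates with no timezone handling.
* The generator's channel distributions are plausible inventions; results
  on it bound nothing about real cohorts.
* Chained-equation imputation uses ridge linear models throughout; no
  per-column model selection.
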