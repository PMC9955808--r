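---
title: "Quantitative MAS grading from instrumented passive elbow stretches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MAS grading from instrumented passive elbow stretches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spastimas)
```

## The measurement problem

Spasticity — a velocity-dependent increase in muscle tone caused by a
hyperexcitable stretch reflex — is graded in clinics on the Modified
Ashworth Scale (MAS), an ordinal scale with six grades
(`0 < 1 < 1+ < 2 < 3 < 4`). The grading is done by feel: the clinician
stretches the patient's relaxed arm and judges where in the range of motion
(ROM) the characteristic *catch* (a jerk-like spike of resistance) occurs
and how hard the limb resists. This makes the scale notoriously
rater-dependent.

`spastimas` implements an instrumented version of that examination. One
assessment session records three slow and then three fast passive elbow
stretches with three sensors: a twin-axis goniometer (joint angle in two
planes, 1000 Hz), a handheld myometer (resisting force in newtons, 1000 Hz)
and a surface-EMG electrode on the biceps (2000 Hz). From those signals the
package isolates each stretch, finds the catch, computes 17 features, and
predicts the MAS grade with a rule-plus-classifier cascade
(Logical–SVM–RF).

## Signal conditioning

Each channel gets a fixed cleaning chain, applied exactly once:

* **Angle** — the two goniometer planes are combined into the resultant
  elbow angle $\theta = \sqrt{\theta_x^2 + \theta_y^2}$, then a 5th-order
  median filter (spike removal) and a 5th-order mean filter (smoothing).
* **Force** — the same median/mean pair, then *fix-zero levelling*: the
  mean of the first 100 ms (arm at rest, clinician not yet engaged) is
  subtracted, removing the sensor's resting offset. The 100 ms baseline
  window is the package's estimator choice for this step.
* **sEMG** — mean removal, full-wave rectification, then a 4th-order 10 Hz
  low-pass Butterworth producing the muscle-activity envelope. The filter
  runs forward–backward (zero phase) so the envelope peak is not delayed
  relative to the mechanical catch; the envelope is then decimated 2:1 onto
  the 1000 Hz time base (the 10 Hz low-pass is the anti-aliasing filter).

Edges of the sliding filters are handled by mirror reflection. The chain is
deliberately not idempotent; the pipeline applies it once and the tests
assert single application.

## Stretch segmentation

Stretches are found as rising phases of the angle signal between
alternating local minima and maxima. The detector works at two scales:

1. *Coarse detection.* An additional 50 ms mean smoothing is applied (for
   detection only) and extrema are kept if the rise between a minimum and
   the following maximum exceeds a prominence threshold (default 10°).
   Weak adjacent extremum pairs are pruned iteratively, smallest first.
2. *Boundary localisation*, on the full-resolution signal: each boundary is
   snapped to the last sample still within 5 session-noise-sigmas of the
   flanking plateau. The noise sigma is the median of the quietest quarter
   of 100 ms block standard deviations, which is exactly zero for
   noise-free plateaus — so noise-free boundaries are recovered exactly,
   and noisy plateaus cannot drag a boundary around. With `refine = TRUE`
   each boundary is additionally re-localised as the intersection of two
   local line fits flanking the corner, which is the recommended setting
   for low-SNR recordings.

Two choices deserve mention. The prominence threshold adapts downwards to
35 % of the session's angular range, because grade-4 sessions have ROM
below 10° by definition and a fixed 10° threshold would find no stretches
at all — the cascade could then never grade the very patients its ROM rule
exists for. And slow/fast tags are assigned by protocol position (first
three slow, last three fast) rather than by measured velocity, because the
assessment protocol fixes that order; a velocity-based sanity check warns
if the tags look implausible. The peak velocity used by that check is a
±25 ms central difference, which is robust to sample-level differentiation
noise.

## Catch detection and features

The catch is defined as the instant of maximum deceleration: the minimum of
the angular acceleration of the (filtered) segment angle, searched in the
interior 90 % of the segment (a 5 % guard band at each end avoids endpoint
differentiation artefacts), ties breaking earliest. The acceleration is
estimated with central differences over a ±10 ms window rather than
adjacent samples: differentiating twice at single-sample scale amplifies
measurement noise by the squared sample rate, which would let noise rather
than the catch decide the minimum, while a 10 ms window preserves the
catch's 20–40 ms deceleration transient essentially unshifted. A catch event
is *always* returned — for a non-spastic stretch it is simply the ordinary
movement deceleration, and its force context (for example the ratio of
force at the catch to initial force) is exactly what separates non-spastic
from spastic arms downstream.

Seventeen features are computed per stretch: eight kinematic (ROM, catch
angle, angle at maximum sEMG, angle at maximum force, their ratios to ROM,
and maximum angular velocity), six kinetic (force-at-catch over initial
force, normalised force increment at catch, normalised average force before
and after the catch, and least-squares force slopes after the force maximum
and after the catch), and three physiological sEMG features (normalised
sEMG at catch, normalised average and normalised average slope after the
catch). Clinically the force-at-catch/initial-force ratio is counted in
both the kinetic and the physiological group, giving the familiar 8/6/4
grouping; `feature_groups()` reports that grouping with the shared feature
flagged, while the unique feature count is 17.

Conventions chosen by this package (the definitions leave them open):
angles enter the features as *excursion from the segment-start angle*, so
catch-position ratios live in [0, 1] and compare across patients; the
initial force is the mean over the first 5 % of the segment; every "slope
after X" is an ordinary least-squares slope over the full post-event
window; every "normalised" quantity is divided by the within-segment
maximum of its channel, which makes those features invariant to channel
gain — an invariance the tests assert.

## Dataset preparation

Only fast stretches are used for classification (the catch is
velocity-dependent). The split into training and held-out test rows is
stratified by grade at a 90:10 ratio using largest-remainder allocation, so
the test total is `round(0.1 n)` and every grade with at least two rows is
represented. Splitting is by stretch row, which mirrors how the reference
clinical evaluation counted its samples; a stricter subject-grouped mode is
available (`group_by_subject = TRUE`) for leakage-free evaluation at the
patient level. Features are standardised (mean removal, unit population
variance) with parameters fitted on the training rows only, after the
split. Class imbalance is then corrected by random oversampling (ROS,
duplicate minority rows to the majority count) — the default, which
performed best in the reference evaluation — or SMOTE (synthetic rows as
convex combinations of same-class nearest neighbours); the scaler is always
fitted before upsampling. MAS 4 rows are excluded from classifier training
entirely: that grade is decided by a rule, below.

## Classifiers and the Logical–SVM–RF cascade

Five baseline families are supported with tuned hyperparameter defaults:
Gaussian naive Bayes (variance smoothing 0.1203), a decision tree (entropy
splits, minimum 3 leaf / 6 split samples), a random forest (25 trees, Gini,
3 features per split), XGBoost (gbtree, 100 rounds, learning rate 0.1,
gamma 0.1, minimum child weight 5) and an RBF SVM (C = 15, gamma "scale").
Hyperparameter names follow the common Python scikit-learn vocabulary so
the tuned settings transfer verbatim; where an R engine has no equivalent
(rpart has no `splitter` or `max_features`; randomForest is Gini-only and
has no `min_samples_split`) the setting is ignored with a warning and
recorded on the model. The SVM's "scale" gamma is computed exactly as
`1 / (n_features * Var(X))` with the population variance of the whole
design matrix. Exhaustive grid search over the published ranges with
stratified cross-validation scored by balanced accuracy (mean per-class
recall; equal to plain accuracy once classes are balanced) is available via
`grid_search()`.

The cascade routes each stretch through three stages:

1. **ROM rule** — if the range of motion is strictly below 10°, the grade
   is 4, immediately. The threshold sits comfortably above the largest ROM
   observed clinically for grade 4 (7.09°).
2. **SVM stage** — a 5-class SVM is consulted; its answer is *accepted*
   only if it is grade 1 or 3, the grades it separates best.
3. **RF stage** — otherwise a 5-class random forest's class probabilities
   are masked to grades {0, 1+, 2}, renormalised, and the argmax returned.

Both sub-models are ordinary five-class models with post-hoc role
restriction; masking plus renormalisation is this package's reading of the
cascade, since specialised sub-models are not described. Probability ties
in the masked RF stage break toward the lower grade — the clinically
conservative choice. Consequences that the tests pin down: the cascade
never outputs grade 4 when ROM ≥ 10°, and grades 1 and 3 can only come
from the SVM stage.

## The synthetic session generator

No public dataset of instrumented MAS sessions exists, so the package
ships a generator that emulates the assessment protocol with planted ground
truth: minimum-jerk angle rises separated by rest plateaus, with a
localized velocity dip at the planted catch (giving the catch detector a
differentiable, known target); a resisting-force channel that ramps to a
tone baseline on engagement and steps multiplicatively at the catch; and an
sEMG channel with a burst at the catch. Profiles per grade encode the
ordinal clinical structure: grade 1 catches at the end of the range
(fraction 0.82–0.95 of ROM), 1+ in the second half (0.55–0.78), 2 in the
first half (0.15–0.45); grade 0 has no catch and unit force gain; grade 3
has reduced ROM (35–70°), high constant tone and suppressed velocity;
grade 4 has ROM capped at 7.09° — entirely below the 10° rule. Default
noise levels (0.1° angle, 0.3 N force, 12 µV sEMG) are plausible for this
sensor class. All numbers are fixture parameters chosen for that ordinal
structure; they are synthetic by design and are not estimates of any
clinical population.

What passing tests on this generator do show: the pipeline recovers planted
boundaries (±10 ms noise-free), ROM (±1°), catch position (±0.05 of the
ROM fraction) and force gain (±10 %), and the cascade recovers the planted
grades almost perfectly. What they do not show: performance on real
patients — real sessions have tremor, co-contraction, variable clinician
technique and label noise, none of which the generator attempts to model.

## Numerical and evaluation choices

Metric arithmetic follows the standard definitions (per-class precision,
recall, F-measure; accuracy as confusion trace over total; balanced
accuracy as weighted mean per-class recall). Zero-division cases report 0
with an explicit flag. Weighted averages are computed from unrounded
per-class values and rounded once, half-up, to two decimals — the order
that reproduces the published tables; rounding first does not.
`reconstruct_counts()` inverts rounded published precision/recall back to
the unique integer confusion counts, which is how the package verifies
published summary rows exactly. The bundled reference table reproduces the
per-class metrics of the five baselines on their 28-row clinical test set
(supports 7, 9, 7, 2, 2 for grades 0–3, plus one grade-4 row). The
cascade's published evaluation reports 33 cases with three errors (91 %
accuracy), which is internally inconsistent with that 28-row split; the
package reproduces the baseline tables exactly from the 28-row supports and
the cascade headline from its own printed 30-of-33 counts, and documents
rather than resolves the discrepancy.

Problem sizes used by the automated checks were chosen to keep the full
suite in the low minutes on one core: the end-to-end experiment uses 30
synthetic sessions per grade (540 fast stretches) and ten stratified
splits; unit fixtures use seconds-long signals.

## Known limitations

* Segmentation assumes the protocol's rest–stretch–rest structure; free
  movement between stretches would need different windowing.
* `max_angular_velocity` is a sample-level derivative maximum and therefore
  noise-biased upward on low-velocity stretches; the internal speed sanity
  check uses a 50 ms derivative instead, but the feature keeps its
  plain definition.
* The cascade's sub-models are trained on stretch-row splits; with few
  subjects per grade, subject-grouped splitting is the more honest
  evaluation and is provided as an option.
* MAS is ordinal and the classifiers ignore that ordering; no ordinal
  regression formulation is attempted.
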