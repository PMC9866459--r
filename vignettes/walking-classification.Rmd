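---
title: "Classifying walking from a back-worn accelerometer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying walking from a back-worn accelerometer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Older adults with dementia-related gait disorders are monitored in care homes
with a single triaxial accelerometer worn on the mid back — a placement chosen
because visible sensors tend to be removed by the wearer. The sensor samples
slowly (11 Hz) to stretch battery life over weeks. The analysis task is
binary: decide, for every few seconds of signal, whether the wearer was
walking. Two things make this harder than textbook activity recognition: the
back placement attenuates and mixes the gait oscillation, and walking-aid
users (walkers, crutches, sticks) walk slowly and asymmetrically, so cadence
and amplitude vary widely across subjects. Recordings also contain far more
sitting, standing and fidgeting than walking, so the positive class is rare.

`backgait` implements the complete pipeline: windowing, feature extraction,
wrapper feature selection, minority oversampling, four classifiers, and
subject-wise evaluation, plus a cohort simulator that stands in for clinical
data, which is typically not shareable.

## Windowing and labelling

Recordings are cut into windows of 3, 6 or 9 s with 50% overlap; 6 s is the
default because windows of 5–6 s are the clinically accepted unit for human
walking analysis. The window length in samples is `w = round(window_s * fs)`
and the stride is `floor(w / 2)` — for odd `w` (3 s at 11 Hz gives 33
samples) this keeps at least half overlap and stays deterministic. Trailing
samples that do not fill a window are dropped; indexing is 0-based. A window
is labelled *walking* only if strictly more than half of its samples are
walking; exact ties go to *other*. Windows that straddle an activity boundary
are kept — the majority rule decides them — because excluding them would
remove exactly the transitions a deployed classifier must handle.

## Features

Sixty named feature groups are computed per axis: 16 statistical (moments,
quantiles, ECDF summaries, a fixed 10-bin histogram), 18 temporal (energies,
differences, turning points, zero crossings, slope, peak counts) and 26
spectral (FFT moments, cumulative-power landmarks, cepstral and wavelet
descriptors). Multi-valued groups (ECDF deciles, histogram bins, 12 LPC and
12 mel cepstral coefficients, per-bin spectrogram means, per-level wavelet
summaries) expand to several columns, so one group activates all of its
columns across all three axes during selection. With the default 6 s window
the matrix has 378 columns in 60 groups.

Where a named feature admits several conventions, one was fixed and recorded
in `feature_params()`: ECDF percentiles at 0.2/0.8; quantiles by the inverse
ECDF (type 1) for ECDF features and the usual interpolating type 7 for IQR
and medians; population moments for variance, skewness and kurtosis (excess);
lag-1 normalized autocorrelation; strict local extrema as turning points;
spectral roll-off/roll-on at 85%/5% cumulative power and "maximum frequency"
at 95%; a 0.6–2.5 Hz cadence band for the human-range energy ratio; spectral
entropy normalized to `[0, 1]` and computed without the DC bin so a gravity
offset cannot mask spectral flatness; a Hann-windowed 32-sample STFT for the
spectrogram means; and a 3-level Haar detail pyramid for the wavelet
features (hand-coded — it is twenty lines — and defined exactly in the code).
Degenerate values (0/0 on constant windows, log 0, all-zero spectra) are
imputed to 0 and recorded per cell in the matrix's `imputations` attribute;
this keeps selection and classification total over any input.

Columns are z-scored with means and standard deviations estimated on the
training rows of each fold only. The kNN wrapper and ADASYN's neighbour
search are distance-based, so commensurate scales are a correctness issue,
not cosmetics.

## Feature selection

Selection is a wrapper search over the 60 groups by binary particle swarm
optimization. Particles carry continuous positions and velocities of length
60; velocities follow

    v' = 0.9 v + 2 r1 (pbest - x) + 2 r2 (gbest - x),

clamped to ±4, positions accumulate velocities, and a mask is drawn by the
standard sigmoid transfer (bit on iff `sigmoid(x_j) > u_j`); an all-zero mask
is repaired by forcing the strongest component on. The objective is

    fitness = 0.9 * error + 0.1 * n_selected / 60,

where the error term is the misclassification rate of a 5-nearest-neighbour
wrapper under a 3-fold stratified split of the training rows — the cheapest
member of the pipeline's own model set. The swarm has 30 particles and runs
at most 50 iterations, stopping after 10 without improvement; these horizons
are where the fitness curve flattens on every problem we generate. The
personal and global bests keep the smallest fitness seen, so the global-best
history is non-increasing by construction. For large cohorts the wrapper
evaluates on a stratified subsample of at most 300 training rows drawn once
per selection run; the error estimate stays unbiased for ranking masks while
the wrapper cost stops growing with cohort size. Selection is re-run in every
cross-validation fold (different subjects select different features), seeded
from the master seed and the held-out subject.

## Oversampling

Walking windows are a minority (about 1:3.5 under the default simulator,
worse in clinical data), which biases any loss-minimizing classifier toward
the majority. ADASYN rebalances the *training* rows of each fold: the number
of synthetic points is `round(target_ratio * n_majority) - n_minority`
(target ratio 1 by default); each minority row is weighted by the fraction of
majority points among its K = 5 nearest neighbours in the full training set,
so synthesis concentrates near the class boundary; integer per-row counts
come from largest-remainder rounding, so the total is exact. Each synthetic
point is `x_i + (x_k - x_i) * lambda` with `x_k` uniform among the row's K
nearest *minority* neighbours and `lambda ~ U(0, 1)` — the classical reading
of the method's neighbour steps, which is ambiguous about the neighbour pool;
we use all-class neighbours for the density weights and minority-only
neighbours for interpolation. Every synthetic row records its parent row,
neighbour row, lambda and parent subject, which is what lets the tests prove
that no synthetic point ever derives from a held-out subject. Validation
rows are never oversampled.

Selection runs before oversampling within each fold; the wrapper error in the
fitness is then estimated on real rows only and cannot be deflated by
interpolated duplicates.

## Classifiers

Four models, identical interface (`train_model()` / `predict()`):

* **kNN**, k = 5, Euclidean, vote share as score;
* **random forest**, 100 trees, `sqrt(p)` features per split;
* **gradient-boosted trees**, 100 rounds, depth 3, learning rate 0.1;
* **stacking ensemble**: the three models above as level-0, a logistic
  regression on their class probabilities as the meta-estimator. Meta-features
  are produced strictly out-of-fold by an internal 5-fold stratified split of
  the training rows; level-0 models are then refit on all training rows. The
  fold bookkeeping is kept in the fitted object so the out-of-fold property
  is auditable after the fact rather than taken on faith.

All hyperparameters are the libraries' canonical defaults, declared in one
place (`model_spec()`); nothing here is tuned. Base learners come from
`class`, `randomForest` and `xgboost`; the stacking procedure itself is
implemented in this package.

## Evaluation

Cross-validation is leave-one-group-out with subjects as groups: every
subject is held out exactly once, and no subject contributes segments to both
sides of a split — within-subject correlation would otherwise inflate every
metric. Per fold we report the confusion matrix (walking positive),
sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy, the balanced
F-score `(1+β²)·PPV·Se/(β²·PPV+Se)` at β = 1, and AUC from a threshold-sweep
ROC (trapezoid, equal to the normalized Mann–Whitney statistic). Metrics with
zero denominators are reported as 0 with a warning. Aggregates are unweighted
means over subjects, not segment-pooled: subjects are the unit of inference
and record lengths differ. A fixed train/test split over subject sets is
available as `run_holdout()`; with a single test subject and the same master
seed it reproduces the corresponding cross-validation fold exactly, because
per-fold seeds are derived from the master seed and the held-out subject's
id rather than from fold position.

## The simulator

`simulate_cohort()` generates labelled recordings so every stage of the
pipeline can be exercised and tested without clinical data. Defaults encode
the target setting: 20 subjects at 11 Hz, durations uniform on 278–527 s,
one contiguous walking bout covering 15–28% of the recording (yielding a
walking:other segment ratio around 0.2–0.4 at 6 s windows), cadences
0.8–2.0 Hz to span aid-assisted slow gait, and sitting/standing plus
"active" fidgeting episodes for the rest. Walking is a cadence sinusoid plus
its first harmonic on the vertical and anteroposterior axes over a unit
gravity offset with Gaussian noise; active episodes have noise bursts but no
sustained cadence; episodes get small orientation jitter. Labels are exact by
construction, which is what makes parameter-recovery experiments meaningful.

The simulator is deliberately not a biomechanical gait model: it has no
double-support timing, no sensor drift or temperature effects, no
diagnosis-specific signatures, and its walking bouts are cleaner than
walker-assisted shuffling. Passing the end-to-end checks therefore shows the
pipeline is implemented correctly and can recover a planted signal under the
stated imbalance and subject heterogeneity — it does not certify clinical
accuracy on real patients, which can only come from real labelled
recordings. Difficulty can be raised by increasing `noise_range` or narrowing
the gap between cadence and fidgeting spectra.

## Problem sizes and determinism

The packaged experiments run at desk scale: the end-to-end checks use an
8-subject cohort of ~350 s recordings at 6 s windows (roughly 850 segments),
selection problems of 60 groups, and 20-run repetitions for the stochastic
selection properties. Every random step — simulation, fold assignment, swarm,
binarization, ADASYN draws, model fits — descends from explicit integer
seeds, and repeated runs with the same master seed produce byte-identical
reports. Internal seeded helpers save and restore the caller's RNG state.

## Known limitations

* The wrapper error inside the selection fitness uses one fixed inner fold
  assignment per selection run; this makes mask comparisons low-variance and
  cheap but slightly favours masks adapted to that assignment.
* ADASYN assumes minority neighbourhoods are meaningful in the standardized
  feature space; with very few walking segments per fold the interpolants
  cluster tightly and add little diversity.
* kNN prediction scores are vote fractions over 5 neighbours, so its ROC has
  few distinct thresholds and its AUC is coarser than the tree ensembles'.
* The unregularized logistic meta-estimator can assign extreme weights when
  level-0 models separate the (oversampled) training rows perfectly; on an
  occasional held-out subject whose score distribution shifts, the stack can
  then trail its own members. A ridge-penalized meta-fit would damp this at
  the cost of departing from the canonical stacking recipe.
* Aggregate metrics weight every subject equally regardless of recording
  length; a subject with few segments contributes as much as a long
  recording, which is intended (subjects are the unit) but worth remembering
  when comparing to segment-pooled numbers.
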