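---
title: "Methods: sensor-based stratification of nonspecific low back pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-based stratification of nonspecific low back pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trunkstrat)
```

## Overview

`trunkstrat` stratifies nonspecific low back pain (NSLBP) patients into
prognostic risk groups from a timed trunk flexion/extension task. The
measurement model is: a chest-worn IMU samples three gyroscope and three
accelerometer channels at 20 Hz (gyro full scale ±2000 deg/s; X is the
flexion/extension axis; accelerometer axes are vertical, mediolateral
and anteroposterior) while a balance board samples the 2-D
centre-of-pressure (COP) trajectory at 40 Hz over the same 14-s trial.
Ground-truth risk labels come from the STarT Back Screening Tool (SBST);
HADS and TSK questionnaire scores supply a psychosocial feature set.
This vignette documents the processing model, the tunable parameters,
the synthetic cohort that makes the pipeline testable, and the numerical
and statistical choices that were genuinely open.

## Preprocessing model

1. **Angular acceleration** is derived from each raw gyroscope channel
   *before* segmentation, by central differences at interior samples and
   one-sided differences at the two ends. Differentiating the raw stream
   matters: after time normalization the velocity profile no longer
   encodes how many cycles a subject performed, but the acceleration
   amplitude still does.
2. **Cycle detection** runs on the flexion/extension gyro axis after a
   4th-order Butterworth low-pass at 1 Hz applied forward-backward
   (zero phase). Only the cutoff is a protocol constant; the filter
   realization is ours, and the zero-phase choice is deliberate —
   causal filtering would delay the zero crossings that define cycle
   boundaries. The forward-backward pass is wrapped in odd-symmetric
   reflection padding (3 / cutoff seconds each side) so start-of-trial
   transients do not corrupt the first boundary. A cycle starts where
   the filtered signal crosses from negative to non-negative; an exact
   zero counts as positive (a deterministic tie-break).
3. **Segmentation** slices the *unfiltered* channels at the detected
   boundaries — the filtered signal exists only to locate starts.
   Partial movement before the first and after the last start is
   discarded, as a partial cycle has no defined normalized time base.
4. **Time scaling** resamples each cycle to 101 points by linear
   interpolation over a uniform parameter in [0, 1]. Linear
   interpolation is the simplest scheme consistent with time scaling
   and preserves endpoints and linear trends exactly; at 20 Hz a cycle
   spans 30–60 raw samples, so spline refinement would be cosmetic.
5. **RMS aggregation** collapses the stack of a subject's cycles into
   one profile: at each of the 101 normalized points, the root mean
   square across cycles. The first point is excluded (all segments
   share their boundary sample), leaving 100 points per channel.
   Aggregated profiles are therefore non-negative; sign information
   survives only through profile shape.
6. **Concatenation** of the nine 100-point profiles in the fixed order
   gyro X/Y/Z, accel X/Y/Z, angular-accel X/Y/Z yields the 900-value
   full-signal (FS) vector.

## Feature sets

* **FS** — the 900-value vector above.
* **FT16** — 16 statistics per channel (144 total): max, min, range,
  mean, quartiles Q1/Q2/Q3, IQR, IQR/median, SD, kurtosis, skewness,
  entropy, power, frequency at maximum power, median frequency.
  Conventions that needed fixing: quartiles by linear interpolation of
  order statistics; kurtosis is the Pearson (non-excess) standardized
  fourth moment and skewness the standardized third (both defined as 0
  for a constant profile); entropy is the Shannon entropy (natural log)
  of a 10-equal-width-bin amplitude histogram with 0·log 0 = 0; power
  is the mean squared profile value; the two spectral features come
  from the periodogram of the 100-point profile with the DC term
  excluded, on a frequency axis in cycles per (normalized) cycle, the
  median frequency being the smallest frequency whose cumulative power
  reaches half the total. When a profile's median is 0, IQR/median is
  reported as a configurable sentinel (default 0) with a warning.
* **Wii** — COP x/y displacement ranges, path length (sum of
  consecutive Euclidean steps) and the 95% prediction-ellipse area
  `pi * 5.991 * sqrt(lambda1 * lambda2)` from the eigenvalues of the
  2×2 COP covariance (5.991 = 95% quantile of chi-squared with 2 df),
  all over the whole trial.
* **ADT** — the HADS-A, HADS-D (0–21) and TSK (17–68) scores; the two
  HADS subscales are kept separate rather than summed, so the
  psychosocial set has three values.

**Normalization.** Features are standardized to mean 0, *sample*-SD 1
across subjects. The scale parameter is the standard deviation, not the
variance: standardization targets a unit-variance scale, and dividing by
the variance would leave features with unequal spread. A population-SD
variant is available (`scale_type = "population"`). Zero-dispersion
columns cannot be scaled and are dropped with a warning; the returned
statistics record the drop so held-out subjects are transformed
identically.

## Clustering

K-means uses squared-Euclidean Lloyd iterations (`stats::kmeans`)
started from k-means++ seeds, 10 restarts, best solution by total
within-cluster sum of squares; a restart whose iteration empties a
cluster is discarded in favour of the remaining restarts. The cluster
count is chosen over k = 2..6 by maximizing the Calinski–Harabasz index
`CH = (SSB/SSW) * (N−k)/(k−1)` with SSB and SSW as between- and
within-cluster sums of squares — the standard sum-of-squares form of
the index, which makes it invariant under uniform rescaling of the
coordinates. `SSW = 0` returns an infinite index with a warning.
Clusters are evaluated by majority labelling: each cluster adopts its
modal risk label (ties to the lexicographically smaller label, with a
warning) and the induced labelling is scored against the truth. The
pipeline scans three standard kinematic feature groups — angular
velocity, linear acceleration, and their combination.

## Classification

* **Tasks.** Each one-vs-rest binary grouping of the three risk classes
  (the singleton class is positive), plus the three-class task.
* **Balanced subsampling.** Two-class tasks keep every minority-class
  subject and draw an equal-sized uniform sample from the majority
  class; 10 such runs (seeds derived from the master seed) are scored
  independently and summarized as mean (sd).
* **LOPO-CV.** Every subject is predicted by a model trained on all
  others. Standardization statistics are re-estimated inside each
  training fold and applied to the held-out subject (default), so the
  held-out row never leaks into its own preprocessing; a `"global"`
  mode reproduces the normalize-then-split reading for comparison.
* **SVM grid.** Linear and 2nd-degree polynomial kernels with
  C ∈ {0.1, 1, 10}, and the RBF kernel with the same C values crossed
  with kernel scale ∈ {0.1, 0.5, 1} (passed as the RBF `gamma`);
  15 cells. The reported configuration is the cell with the highest
  LOPO accuracy, selected on the *same* LOPO loop — deliberately
  optimistic selection semantics (no nested CV), because the reported
  quantity is "the best grid cell's LOPO accuracy". The chance-level
  checks below therefore fix a single cell.
* **MLP.** A feedforward stack of 8 sigmoid hidden layers
  (700-500-300-100-50-15-10-5), softmax output sized to the class
  count, cross-entropy loss, full-batch Adam (step 1e-3), at most 500
  epochs with early stop once the epoch-to-epoch loss change stays
  below 1e-6 for 10 epochs, Glorot-scaled seeded initialization.
  No pre-installed package expresses this fixed multi-hidden-layer
  architecture, so the engine is implemented in plain matrix algebra
  inside the package. Prediction ties break to the lowest class index.
* **Metrics.** Accuracy, sensitivity, specificity, precision (as
  percentages), F1 and G-index. F1 is the harmonic mean of sensitivity
  and precision, `2·Se·Pr/(Se+Pr)`; an alternative form with Se+Sp in
  the denominator is available behind `f1_form` for comparison with
  sources that print it that way. The G-index is the Euclidean
  distance from the ideal point in (sensitivity, precision) space,
  `sqrt((1−Se)^2 + (1−Pr)^2)`; the radical is essential — it makes a
  coin-flip classifier land at `sqrt(0.5) ≈ 0.707`, which is exactly
  the published "random" anchor of 0.70. Quality bands: optimum
  G ≤ 0.25, good 0.25 < G < 0.70, random [0.70, 0.71) (the band
  absorbs the rounding of sqrt(0.5) to 0.70), bad otherwise.
  Zero-denominator metrics are reported as missing, flagged, and
  excluded from mean/sd with an exclusion count.

## The synthetic cohort

No patient recordings are distributed with this kind of study, so the
generator is a first-class module: every downstream stage is developed
and tested against cohorts whose ground truth is known by construction.

**Signal model.** Each cycle is a raised-cosine trunk flexion to the
subject's range of motion (ROM) and back; the flexion/extension gyro
channel is its analytic derivative times a velocity scale; the
accelerometer combines the gravity projection of the instantaneous
sagittal angle with lever-arm motion terms (0.45 m sternum height,
centripetal on the vertical axis, tangential on the anteroposterior
axis) plus white noise; the off-axis gyro channels carry small fixed
cross-talk fractions (0.15, 0.10) of the main axis plus noise; gyro
samples are clipped at ±2000 deg/s. Anteroposterior COP follows the
trunk angle with a gain in cm/deg; mediolateral COP is pure noise.
Within-subject cycle periods are lognormal (positive support) with a
configurable CV; questionnaire scores are rounded truncated-normal
draws. Everything is a pure function of (parameters, seed).

**Study conditions.** The default cohort is 29/37/28 low/medium/high
subjects (the 94-patient clinical cohort's composition), 14-s trials at
20/40 Hz. Group profiles encode the qualitative clinical picture —
high-risk subjects move more slowly (cycle period 2.3 s vs 1.9/1.7),
with smaller ROM (42° vs 50/55°) and lower velocity scale (0.78 vs
0.92/1.0), and score higher on HADS/TSK. Individual subjects jitter
period, ROM and velocity scale lognormally around their group profile
with a between-subject CV of 0.22. No quantitative group effect sizes
exist to copy, so this CV was set as the design point at which the
default high vs low-medium LOPO-SVM lands in the mid-70s accuracy
regime reported for the clinical cohort: large enough overlap that the
task is genuinely hard, small enough that structure is recoverable.

**What it does not emulate.** Sensor drift, bias and orientation error;
gravity/motion cross-contamination beyond the rigid-pendulum terms;
fatigue or learning effects across the trial; any biomechanical detail
the pipeline does not consume. Passing tests therefore show that the
pipeline recovers structure *of the kind injected* under realistic
noise and overlap — they cannot certify performance on clinical data.

## Statistical notes

Two properties of leave-one-out with balanced subsamples shape the
chance-level ("effects zeroed") control:

* Best-of-grid selection is optimistic, so null checks fix a single
  grid cell — otherwise selection inflation (the max of 15 correlated
  chance accuracies) would mask the leakage the check exists to detect.
* The 10 balanced runs reuse the same subjects, so the 560 pooled
  predictions are strongly correlated, and LOPO itself carries a known
  anti-learning bias on signal-free balanced data (the held-out
  subject's class is always the training minority). The chance
  interval is therefore the 95% binomial interval with n equal to the
  number of *distinct* evaluated subjects, not the pooled prediction
  count.

## Problem sizes

The package's own checks run the full 94-subject default cohort with
the complete 15-cell grid for the headline high vs low-medium
experiment, a single-cell grid for the chance control, 100-seed
cluster-count recovery on 30-point blob cohorts, 1000 random stacks for
the aggregation oracle, and a 26-subject cohort with a single-cell grid
for the 15-combination feature-set factorial — sizes chosen so the
whole battery documents the method at desk scale while exercising every
code path at the study's real dimensionality (900–1051 features).

## Known limitations

* The MLP at its full default architecture is slow in pure R at the
  900-feature scale; it is practical for the smaller feature sets or
  reduced architectures, and the SVM is the workhorse classifier.
* Three-class experiments report accuracy and per-class recalls only;
  the binary metric suite (G-index, F1) is not defined there and no
  one-vs-rest collapse is applied.
* Hard labels only: the SVM decision values are not exposed, so no ROC
  sweeping — the G-index is computed from the single
  (sensitivity, precision) operating point, as its definition here
  requires.
* Recordings are assumed time-synchronized at fixed nominal rates; no
  resampling or drift correction is applied beyond what the header
  declares.
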