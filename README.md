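# trunkstrat

Sensor-based risk stratification of nonspecific low back pain (NSLBP).

Clinical guidelines stratify NSLBP patients into **low / medium / high
prognostic-risk groups** (the STarT Back Screening Tool, SBST) because the
high-risk group needs a markedly different treatment program. `trunkstrat`
implements a complete, reproducible pipeline that asks whether that
stratification can be read out of *movement* instead of questionnaires: a
chest-worn IMU (3-axis gyroscope + accelerometer, 20 Hz) records a timed
14-s trunk flexion/extension task, a balance board records the
centre-of-pressure (COP) trajectory (40 Hz), and machine-learning models
map the resulting movement signature onto the risk groups. It is intended
for biomechanics and clinical-ML researchers who want to study, extend or
stress-test this kind of sensor-based stratification without access to
patient data: a first-class synthetic-cohort generator produces recordings
with configurable, risk-group-dependent kinematic and psychometric
structure.

## The method

**Cycle aggregation.** Flexion/extension cycles are detected on the 1
Hz-low-passed flexion/extension gyroscope axis at negative-to-positive
zero crossings. All nine kinematic channels (angular velocity, linear
acceleration and derived angular acceleration, each in X/Y/Z) are sliced
at the same boundaries, every cycle is linearly time-scaled to 101 points,
and the cycles of a subject are collapsed into a single 100-point profile
by the root mean square across cycles at each normalized time point
(the shared first point is dropped):

```
C_i = sqrt( (C_i1^2 + C_i2^2 + ... + C_in^2) / n )
```

**Feature sets.** Four sets, combinable factorially (2^4 − 1 = 15 cases):

| set  | content                                               | size |
|------|-------------------------------------------------------|------|
| FS   | the nine concatenated 100-point profiles              | 900  |
| FT16 | 16 summary statistics per channel (order statistics, moments, entropy, power, spectral) | 144 |
| Wii  | COP x/y range, path length, 95% prediction-ellipse area | 4   |
| ADT  | HADS-anxiety, HADS-depression, TSK scores             | 3    |

All features are z-scored across subjects before learning.

**Unsupervised structure.** K-means (k-means++ seeding, 10 restarts) over
k = 2..6; the cluster count maximizes the Calinski–Harabasz index
`CH = (SSB/SSW) · (N−k)/(k−1)`; clusters are scored by majority risk
label.

**Supervised classification.** Leave-one-participant-out (LOPO)
cross-validated SVMs over a kernel/hyperparameter grid (linear,
2nd-degree polynomial, RBF; C ∈ {0.1, 1, 10}; RBF scale ∈ {0.1, 0.5, 1}),
plus an 8-hidden-layer MLP baseline. Two-class tasks (e.g. high vs
low-medium) are repeated over 10 balanced subsamples of the majority
class and reported as mean (sd) of accuracy, sensitivity, specificity,
precision, F1 and the G-index
`G = sqrt((1−Se)^2 + (1−Pr)^2)` (0 = perfect, ≈0.70 = random).

## Worked example

```r
library(trunkstrat)

cohort <- generate_cohort(cohort_config(seed = 1))
cohort
#> <trunk_cohort> 94 subjects (low 29 / medium 37 / high 28)

fs   <- assemble_feature_set(cohort_features(cohort), "FS")
norm <- normalize_features(fs)$features

scan <- scan_cluster_number(norm, k_range = 2:6, seed = 1)
tidy(scan)
#> # A tibble: 5 × 4
#>       k ch_index    ssb    ssw
#>   <int>    <dbl>  <dbl>  <dbl>
#> 1     2     42.6 26490. 57210.
#> 2     3     31.4 34187. 49513.
#> 3     4     23.9 37112. 46588.
#> 4     5     19.2 38815. 44885.
#> 5     6     16.6 40642. 43058.

exp <- run_experiment(fs, cohort$manifest,
                      grouping = "high_vs_lowmedium",
                      classifier = "svm",
                      svm_grid = default_svm_grid(costs = c(0.1, 1, 10))[1:3, ],
                      n_balance_runs = 10, seed = 1)
exp$summary[, c("metric", "formatted")]
#> # A tibble: 6 × 2
#>   metric      formatted
#> 1 accuracy    76.8 (4.2)
#> 2 sensitivity 79.3 (3.7)
#> 3 specificity 74.3 (7.3)
#> 4 precision   75.8 (5.7)
#> 5 f1          0.77 (0.04)
#> 6 g_index     0.32 (0.05)
```

Reading the output: the Calinski–Harabasz curve peaks at k = 2 — the
kinematic data support two natural groups, not three, matching the
clinical intuition that high-risk patients are the distinct population.
The high vs low-medium SVM then recovers the injected group structure at
76.8% mean accuracy over the 10 balanced runs, with a G-index of 0.32
("good" band: clearly better than random at 0.70, short of the optimum
band at 0.25). `autoplot(scan)` and `autoplot(exp)` draw the
index-versus-k curve and per-run metric spread.

The whole chain, including the report bundle on disk, is one call:

```r
run_pipeline(pipeline_config(cohort = cohort_config(seed = 1),
                             out_dir = "run1", seed = 1))
```

and a thin CLI over the same functions lives in `inst/cli/trunkstrat.R`
(`Rscript inst/cli/trunkstrat.R run --out run1 --seed 1`, with
`simulate / preprocess / featurize / cluster / classify / evaluate`
subcommands for stage-wise use).

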