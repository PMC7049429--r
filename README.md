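# kneegait

Spatiotemporal gait analysis from knee-worn triaxial accelerometers, with
Tinetti mobility-test scoring and Parkinson's disease (PD) vs. healthy older
group (HOG) classification.

## The problem

Gait disturbance is a cardinal motor sign of Parkinson's disease, but
laboratory systems (3D motion capture, instrumented walkways) are expensive
and confined to the clinic. A knee-worn triaxial accelerometer (±8 g, 32 Hz)
is cheap and wearable all day — if its raw signal can be turned into the five
spatiotemporal gait characteristics clinicians actually use: **step time,
stride time, step length, stride length and walking speed**. `kneegait`
implements that estimation chain, validates it against reference parameter
tables, scores the Tinetti mobility test, and classifies PD vs. HOG subjects
from the five estimated characteristics. A ground-truth-annotated synthetic
walking-signal generator makes every stage testable without recorded data.

## The method

For each recording (one file per subject per leg, axes X = medial-lateral,
Y = anterior-posterior, Z = vertical):

1. **Dynamic tilt correction** — two planar rotations driven by the channel
   means re-align the sensor with gravity, nulling the mean AP and ML
   accelerations.
2. **Vertical signal** — the recording-mean vertical value (gravity) is
   subtracted, g is converted to m/s², and a zero-phase 4th-order Butterworth
   low-pass at 15 Hz is applied.
3. **Initial-contact (IC) detection** — the filtered signal is integrated
   (trapezoidal, drift-detrended) and differentiated with a continuous
   wavelet transform using a first-derivative-of-Gaussian wavelet; heel
   strikes appear as minima of the transformed series. A refractory period
   (0.25 s) and a prominence threshold suppress spurious minima.
4. **Temporal parameters** — consecutive ICs at the knee are alternating-foot
   contacts, so

       step time_i   = IC_{i+1} − IC_i
       stride time_i = IC_{i+2} − IC_i

5. **Spatial parameters** — the extended inverted-pendulum model maps the
   sensor's vertical excursion H (max − min of the double-integrated vertical
   acceleration between two ICs) to

       step length   = K_I · 2 · √(2·W_h·H − H²)      (W_h = 0.34 m, K_I = 4)
       stride length = 2 · step length
       walking speed = mean step length / mean step time

Validation uses the absolute percentage error
`|estimated − reference| / reference × 100` per subject and Pearson
correlation between paired estimates. Classification compares four
classifiers (5-NN, RBF-kernel SVM, Gaussian naive Bayes, pruned Gini
decision tree) under stratified 70:30 subject-wise resampling
cross-validation, with PD as the positive class.

## Worked example

```r
library(kneegait)

## one synthetic walk with 3% sensor noise, estimated back
aw <- simulate_walk(walk_spec(n_steps = 16, noise_sigma_rel = 0.03, seed = 42))
estimate_gait(aw$recording)
#> <gait_parameters> subject sim, left leg (16 steps)
#>   step time 0.561 s, stride time 1.120 s, step length 0.377 m,
#>   stride length 0.755 m, walking speed 0.673 m/s
as.data.frame(aw$truth_params)[, 3:7]
#>   step_time_s stride_time_s step_length_m stride_length_m walking_speed_mps
#> 1   0.5598743      1.118389      0.367074        0.734148         0.6556365
```

The estimate recovers the programmed walk to within a few percent: step time
0.561 s vs. 0.560 s true, step length 0.377 m vs. 0.367 m true.

```r
## a 20-subject cohort: validation against ground truth, then classification
co  <- simulate_cohort(n_pd = 10, n_hog = 10, seed = 1)
est <- estimate_cohort(co)
validation_report(est, co$truth)[1:5, ]
#>           parameter  leg  n mean_error_pct sd_error_pct pearson_r  p_value
#> 1       step_time_s left 20         0.1630       0.0613         1 1.41e-35
#> 2     stride_time_s left 20         0.0883       0.0366         1 2.24e-39
#> 3     step_length_m left 20         2.7634       0.1886         1 6.01e-34
#> 4   stride_length_m left 20         2.7634       0.1886         1 6.01e-34
#> 5 walking_speed_mps left 20         2.5961       0.1531         1 1.46e-37

ft <- build_features(est, co$subjects)
cv <- cross_validate(ft, n_splits = 5, seed = 1)
aggregate(cbind(accuracy, sensitivity, specificity_std) ~ model, cv, mean)
#>           model accuracy sensitivity specificity_std
#> 1 decision_tree    0.800       0.867           0.733
#> 2   gaussian_nb    0.933       0.933           0.933
#> 3          knn5    0.867       0.933           0.800
#> 4       svm_rbf    0.900       0.933           0.867
```

Mean errors stay in the 0.1–3% range per characteristic, and at the default
group separation every classifier recovers the PD/HOG split well above
chance. Tinetti forms are scored with the standard item maxima (balance
9 items / 16 points, gait 8 items / 12 points; totals ≤ 18 = high,
19–23 = moderate, ≥ 24 = low fall risk):

```r
score_tinetti(c(1, 2, 1, 2, 2, 1, 1, 2, 2), c(1, 1, 2, 1, 1, 1, 2, 1))
#> <tinetti_form> subject NA: balance 14/16, gait 10/12, total 24/28 (low fall risk)
```

## Command line

A thin CLI wraps the same functions
(`inst/cli/kneegait.R`, located after installation via
`system.file("cli", "kneegait.R", package = "kneegait")`):

```sh
Rscript kneegait.R simulate --out cohort/ --n-pd 48 --n-hog 40 --seed 1
Rscript kneegait.R estimate --in cohort/ --out params.csv
Rscript kneegait.R validate --params params.csv --ref cohort/truth_params.csv --out report.csv
Rscript kneegait.R classify --params params.csv --subjects cohort/subjects.csv --out metrics.csv
Rscript kneegait.R tinetti  --in forms.csv --out scored.csv
```

Exit codes: 0 ok, 1 data error, 2 usage/config error. A YAML `--config` can
override filter, detection and pendulum settings.

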