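---
title: "Methods: gait-parameter estimation from a knee-worn accelerometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait-parameter estimation from a knee-worn accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneegait)
```

## Scope and signal model

`kneegait` estimates five spatiotemporal gait characteristics — step time,
stride time, step length, stride length and walking speed — from a single
triaxial accelerometer worn on each knee at height $W_h = 0.34$ m above the
ground, sampling at 32 Hz over a ±8 g range (the package accepts any rate;
the synthetic generator defaults to 100 Hz for numerically clean tests).
Axes map X → medial-lateral (ML), Y → anterior-posterior (AP),
Z → vertical (V). Acceleration is stored in the sensor's native unit (g) and
converted to m/s² only inside integration steps.

The chain is: tilt correction → gravity removal and low-pass filtering →
integration → wavelet differentiation and minima picking (initial contacts)
→ temporal parameters from IC differences → spatial parameters from the
inverted-pendulum model.

A key modelling assumption is that a knee-worn sensor registers the heel
strikes of *both* feet, so consecutive detected ICs are alternating-foot
contacts. This is what makes $IC_{i+1}-IC_i$ a step time and
$IC_{i+2}-IC_i$ a stride time. The assumption cannot be verified from a
single-sensor recording itself; the synthetic generator produces signals
consistent with it, and the per-leg estimates are reported separately so a
violation would surface as a left/right inconsistency.

## Tilt correction

Knee mounting is never perfectly aligned with gravity. The correction
applies two successive planar rotations computed from the channel means:
first in the AP–V plane by $\theta_{AP}$, then in the ML–V plane by
$\theta_{ML}$. The angles are computed with `atan2` of the channel means
($\theta_{AP} = \mathrm{atan2}(\overline{a}_{AP}, \overline{a}_V)$), which
coincides with $\arcsin(\overline{a}_{AP}/\lVert\overline{\mathbf a}\rVert)$
for a pure single-plane tilt but still nulls both horizontal means *exactly*
when pitch and roll are combined. That exactness is what makes the
correction idempotent to machine precision — a property the tests assert.
Rotations preserve the per-sample acceleration norm, and a non-positive mean
vertical component (sensor inverted, or an all-zero signal with no gravity
reference) is rejected as an orientation error.

Gravity is then estimated as the recording mean of the corrected vertical
channel — a static-plus-walk average, not a per-stride estimate — subtracted,
and the residual converted to m/s².

## Filtering

A 4th-order Butterworth low-pass at 15 Hz is applied forward-backward
(`signal::filtfilt`), so the filter is zero-phase and IC timings are not
delayed. At the device rate of 32 Hz the cutoff sits just below the 16 Hz
Nyquist frequency, so the filter removes only a narrow top band; at the
simulator's 100 Hz it provides genuine smoothing. The cutoff is exposed
(`filter_spec(cutoff_hz = ...)`) and validated against Nyquist. Gravity
subtraction precedes filtering; the two operations are linear and commute,
but the implemented order is recorded in the output provenance.

## Initial-contact detection

The filtered vertical acceleration is integrated (cumulative trapezoid) and
the least-squares line removed, leaving a drift-free vertical velocity. The
velocity is then differentiated by correlation with a
first-derivative-of-Gaussian wavelet at a single scale $s$ (default
$f_s/10$ samples, a smoothing window on the step-frequency timescale):

$$W(t) = \int v(\tau)\,\psi\!\left(\frac{\tau - t}{s}\right)\mathrm d\tau,
\qquad \psi(u) = -u\,e^{-u^2/2}.$$

$\psi$ is the literal derivative of the standard Gaussian, so $W$
approximates the *negative* smoothed derivative of the velocity, i.e. the
negative smoothed acceleration. At a heel strike the sensor's height is
minimal and its vertical acceleration maximal, so initial contacts appear as
**minima** of $W$. The sign convention is a free choice (axis polarity is
not standardized across devices); it is fixed here so that the detection
rule "pick the minima" is literally true for the package's axis convention.

Three guards make the minima picking robust, with defaults chosen on gait
physiology rather than fitted to data:

| Parameter | Default | Rationale |
|---|---|---|
| CWT scale | $f_s / 10$ samples (0.1 s) | smooths at roughly the step-frequency timescale |
| refractory period | 0.25 s | shortest plausible human step time (typical elderly means ≈ 0.55 s) |
| prominence | 10% of RMS($W$) | suppresses noise minima without touching genuine contacts |

Minima closer together than the refractory period are merged keeping the
deeper one; events within half a refractory period of either recording
boundary are discarded. A signal with no surviving minima yields an empty
event set with a warning, not an error. Detection is translation-equivariant
and amplitude-invariant (minima locations do not depend on signal scale),
both asserted as properties.

## From excursion to step length

For each consecutive IC pair the vertical acceleration segment is
double-integrated with integration constants reset to zero at the window
start, and the displacement segment is linearly detrended. Two drift
controls are deliberate:

* the *segment mean* of the acceleration is removed before integrating —
  over a complete IC-to-IC arc the true mean vertical acceleration vanishes
  (the vertical velocity is zero at both heel strikes), so a residual mean
  reflects gravity-estimate bias and would otherwise grow quadratically
  under double integration;
* the linear detrend of the displacement absorbs any remaining
  integration-constant error.

The excursion $H = \max - \min$ of the resulting displacement feeds the
extended inverted-pendulum model: the body vaults over the stance leg like
an inverted pendulum of effective length $W_h$, and a drop $H$ corresponds
to a chord $\sqrt{2 W_h H - H^2}$. With the dimensionless factor $K_I$
mapping the knee-worn sensor's geometry to the centre of mass,

$$\text{step length} = K_I \cdot 2\sqrt{2 W_h H - H^2}, \qquad
\text{stride length} = 2 \cdot \text{step length}.$$

This is the only dimensionally and geometrically coherent form of the
scaled-chord model, monotone in $H$ on $[0, W_h]$; $H$ outside
$[0, 2W_h]$ (negative radicand) is a domain error. With $W_h$ fixed at
0.34 m, $K_I = 4$ is the corresponding calibration. Whether $K_I$ scales
only the chord or some larger expression cannot be cross-checked against
printed intermediate values (none exist); the chosen reading is recorded in
the provenance and its algebraic inverse
(`invert_pendulum`, $H = W_h - \sqrt{W_h^2 - (L/2K_I)^2}$, the smaller
root) round-trips to $10^{-10}$.

Walking speed is the **ratio of means** — mean step length over mean step
time — not the mean of per-step speeds; both are computable from the
per-step table, but the ratio of means is the reported value. Three
identities therefore hold *exactly* on every output and are asserted on
every test cohort: stride length $= 2\,\times$ step length, speed
$\times$ step time $=$ step length, and stride times are the sums of
adjacent step times.

For classification, the feature vector is the mean of the two legs — a
symmetric choice; per-leg values are reported separately everywhere else.

## Tinetti mobility test

The balance section has 9 items (maxima summing to 16) and the gait section
8 items (maxima summing to 12), each item scored 0/1 or 0/1/2. The per-item
maxima follow the standard performance-oriented mobility assessment
instrument and are validated in code by the two section-sum constraints.
Fall-risk bands partition the 0–28 total: ≤ 18 high, 19–23 moderate,
≥ 24 low. The bands only reference totals up to 28, so the partition is
total and monotone — both asserted.

## Validation statistics

Per-subject error is $|est - ref|/ref \times 100$. The absolute value is a
deliberate choice: a signed version would let errors cancel in the mean,
whereas the reported quantity is an error *rate* with a spread — the
per-subject distribution's mean ± sd is what the validation report tabulates
(averaging per-subject errors, not comparing means of means). Pearson $r$
with its two-sided $t$-based $p$-value comes from `stats::cor.test`, with
legs kept as separate observations in per-leg reports.

## Classification

Four classifiers, PD as the positive class throughout:

* **5-NN** (`class::knn`) on features z-scored with training-set statistics;
* **SVM, radial-basis kernel** (`e1071::svm`), cost 1, $\gamma = 1/(d
  \cdot \mathrm{var})$ of the standardized training matrix, also z-scored;
* **Gaussian naive Bayes** (`e1071::naiveBayes`), raw features;
* **decision tree** (`rpart`), Gini splitting, cost-complexity pruning at
  the complexity parameter minimizing the internal 3-fold cross-validation
  error.

Standardization is fitted on the training subjects only — distance and
kernel methods need comparable feature scales, and using evaluation data
would leak. The stratified 70:30 split draws
$\mathrm{round}(n \cdot 0.3)$ evaluation subjects with per-class allocation
by rounding (adjusted on the largest class); an 88-subject cohort of
48 + 40 yields 62 training and 26 evaluation subjects (14 + 12). The
5-split cross-validation performs five *independent* seeded stratified
resamples of that kind — repeated random subject draws, not a partition —
and every split is subject-wise: all data of a subject stay on one side.

Metrics are accuracy, sensitivity $tp/(tp+fn)$, standard specificity
$tn/(tn+fp)$, NPV $tn/(tn+fn)$ and PPV $tp/(tp+fp)$. Both the standard
specificity and the NPV are always reported because clinical reports
sometimes label NPV as "specificity": on the counts $tp=13, fn=1, tn=10,
fp=2$ the two differ (0.833 vs. 0.909), and carrying both avoids silently
committing to either convention. Zero denominators yield `NA` flags, never
errors.

## The synthetic-walk generator

The generator exists so that every stage has a ground-truth oracle. Its
displacement model is one raised-cosine arc per step: within step $i$ of
duration $T_i$ and excursion $H_i$,
$h(t) = (H_i/2)\,(1 - \cos 2\pi t/T_i)$ — minimal at the step boundaries
(heel strikes), maximal at mid-stance, smooth and twice differentiable in
closed form. The acceleration channel is the *exact* second derivative, so
no numerical differentiation error enters the fixture. Step durations and
lengths are truncated-normal draws (floors 0.25 s and 0.05 m); excursions
are the pendulum inverse of the drawn lengths, so the truth parameters
satisfy all estimator identities exactly. Gravity is added, a static tilt
rotates part of it into AP/ML, and seeded white noise is added to all three
channels at a chosen fraction of the dynamic-signal RMS.

Walks are flanked by 0.5 s standing pads. The outer steps' cosines continue
into the pads under a Gaussian decay envelope ($\sigma = T/4$), emulating
the smooth weight-shift of gait initiation and termination; this keeps the
acceleration continuous at the first and last heel strike (an abrupt
flat-to-cosine junction would shift the smoothed extremum there by 2–3
samples) while lying entirely outside every IC-to-IC window, so truth
parameters are unaffected.

Cohort presets were fixed once, before any end-to-end measurement, and are
not tuning knobs: the healthy-older-group preset uses a 0.55 s mean step
time and 0.37 m mean step length, matching typical reference
motion-capture means for elderly cohorts walking a short track at
comfortable pace; between-subject standard deviations are 0.03 s and
0.025 m and within-walk ones 0.02 s and 0.01 m, reflecting an age-matched
cohort on a fixed 6 m walkway. The PD preset multiplies step length by a
separation factor (default 0.85 — shortened steps in the medicated "on"
state), with walking speed following through the length/time ratio; true
per-group effect sizes are not published for this design, so the factor is
explicitly a simulator parameter, never a claim about a real cohort.
Demographics are drawn from normal approximations of the two cohorts' summary
statistics (PD age 70.6 ± 9.5, UPDRS-III 20.9 ± 12.3, H&Y 2.1 ± 0.74,
disease duration 35.5 ± 27.1 months; HOG age 69.4 ± 7.4 with UPDRS-III and
duration fixed at 0).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: turning, festination and freezing episodes, asymmetric
or variable arc shapes, cadence drift, soft-tissue artefact, sensor
saturation, or any coupling between the ML/AP channels and gait. The
generator is a model of the same pendulum kinematics the estimator assumes,
so end-to-end recovery tests demonstrate internal consistency and numerical
correctness of the chain, not clinical validity.

## Numerical choices and degenerate inputs

* Trapezoidal integration throughout (`pracma::cumtrapz`); drift handled by
  least-squares detrending as described above.
* CWT edges use reflection padding; output length equals input length.
* Event matching is greedy nearest-neighbour one-to-one within a tolerance,
  with the boundary made float-safe (inclusive at the stated tolerance).
* Ties in refractory merging resolve to the deeper minimum; ties in k-NN
  voting resolve by `class::knn`'s all-tied-neighbours rule, which makes the
  degenerate all-identical-features case deterministically predict the
  majority class.
* Recordings shorter than two samples, windows shorter than three samples,
  event sets too small for a step or stride, single-class training sets and
  non-invertible step lengths all raise typed, descriptive errors; an
  event-free signal warns and returns an empty event set instead.
* Seeded routines (`simulate_*`, `stratified_split`, `cross_validate`,
  `fit_predict`) save and restore the caller's RNG state.

## Problem sizes used by the test suite

The suite simulates its fixtures at run time: single walks of 8–20 steps at
100 Hz, cohorts of 4–22 subjects for pipeline round trips, an 88-subject
cohort for split arithmetic and label-permutation nulls, a 40-subject cohort
for the end-to-end simulate–estimate–classify property, and a 10-subject
cohort (3% noise) for the headline error-recovery check, which lands around
2–3% mean error per characteristic — comfortably below the 8% bound asserted.
These sizes are the package's own choice of a compact, fully reproducible
regression suite.

## Known limitations

* The 15 Hz cutoff at the 32 Hz device rate is nearly inert; it matters only
  at higher sampling rates.
* $K_I$ and $W_h$ are fixed protocol constants; per-subject calibration of
  $K_I$ would improve absolute step-length accuracy but requires a reference
  system.
* The alternating-foot IC assumption is untestable from one sensor alone.
* Classifier hyperparameters beyond the stated settings are deliberately not
  searched; the comparison is between off-the-shelf configurations.
* Real-cohort correlation magnitudes and error tables cannot be reproduced
  without the original recordings; the package substitutes property-based
  checks (exact identities, pendulum round trips, permutation nulls,
  monotone separation recovery) for those figures.
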