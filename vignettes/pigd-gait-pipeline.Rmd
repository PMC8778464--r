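---
title: "Methods: thigh-IMU gait analysis and PIGD score regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thigh-IMU gait analysis and PIGD score regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The postural instability/gait difficulty (PIGD) score — the sum of five 0–4
MDS-UPDRS items, range 0–20 — is the standard clinical index of axial
impairment in Parkinson's disease, but it requires an in-person motor
examination. `pigdsense` implements a pipeline that predicts the PIGD score
from a single thigh-worn inertial measurement unit (IMU) recorded during a
7-m timed-up-and-go (TUG) test: stand up, walk, turn, walk back, sit down.
The sensor convention is that, standing, the *y* axis opposes gravity
(median $\alpha_y \approx +1$ g) and *x* lies in the frontal plane, so the
angular velocity $\omega_x$ and the pitch angle $\theta_x$ capture thigh
motion during straight walking.

The pipeline has five stages, each an exported function group:

1. **Orientation** — a Kalman filter fuses $\omega_x$ with the
   accelerometer inclination into $\theta_x$; all channels are then
   band-passed 0.5–20 Hz with a zero-lag Butterworth filter.
2. **Walking-bout detection** — a Morse-wavelet scalogram of $\theta_x$
   over 0.5–2 Hz; the scale-averaged intensity profile above its standard
   deviation marks locomotion.
3. **Stride segmentation** — initial contacts (ICs) are pitch peaks above
   the bout standard deviation, ≥ 0.5 s apart, on the 2 Hz low-passed
   signal; final contacts (FCs) are the most negative minima between
   consecutive ICs; strides run IC→IC.
4. **Features** — 102 per stride: 3 temporal, 11 time-domain statistics and
   6 spectral descriptors for each of $\{\alpha_y, \alpha_z, \omega_x,
   \theta_x\}$, 7 correlation features, and 24 band-energy fractions.
5. **Regression** — per-subject stride averages feed an
   $\varepsilon$-insensitive support vector regression with nested
   leave-one-subject-out (LOSO) hyperparameter optimization over kernel
   function, kernel scale and box constraint; performance is summarized by
   Pearson r, RMSE and MAE on a [0, 1]-normalized target.

## Orientation estimation

The filter state is `[pitch, gyro bias]`. Prediction integrates the
bias-corrected $\omega_x$; correction uses $\hat\theta =
\mathrm{atan2}(\alpha_z, \alpha_y)$. The accelerometer only measures the
gravity direction when the sensor is quasi-static, so the measurement-noise
variance `r_accel` (default $(0.05\ \mathrm{rad})^2$) is inflated 100× when
$|\,\lVert\alpha\rVert - 1\,\mathrm{g}| > 0.1$ g. Process noise defaults:
`q_gyro` $(0.01\ \mathrm{rad/s})^2$ per second of integration, `q_bias`
$(10^{-3})^2$. These were fixed once against the simulator: with a constant
0.5 deg/s bias over 60 s, open-loop integration drifts by bias × time =
30°, while the fused pitch stays below 2° RMSE and the bias state converges
to the injected value. A full quaternion filter is out of scope because
every downstream consumer uses $\theta_x$ only.

## Zero-lag Butterworth filtering

No filter-design package is assumed: the band-pass is designed from the
analog Butterworth prototype by bilinear transform with pre-warped edges,
and applied forward–backward (odd-extension padding, steady-state initial
conditions). Two numerical properties are worth noting, both asserted in
the test suite:

* Measured double-pass gains match the analytic response
  $|H(f)|^4$ to better than 0.5 % in the passband and at the band edges.
  In the deep stopband the digital filter attenuates *more* than the analog
  prototype (frequency warping pushes response toward the zero at Nyquist),
  so stopband agreement is asserted absolutely (±0.05 of unit gain), not
  relatively.
* Forward–backward filtering commutes with time reversal only up to the
  edge-state construction (~1e-4 here); linearity holds to machine
  precision. The padding is 256 samples — the 0.5 Hz corner at 60 Hz has
  transients of hundreds of samples, far beyond the textbook
  3 × (order) rule.

## Walking bouts and contacts

The Morse wavelet uses the conventional symmetry/time-bandwidth pair
$\gamma = 3$, $\beta = 20$. At 1 Hz this wavelet spans roughly ±2.5 s, so
the two 7-m walks of a TUG, separated by a ~2 s turn, merge into a single
detected locomotion bout. The simulator therefore defines its ground-truth
bout as the walk–turn–walk union; strides whose IC pair spans the turn are
*not* excluded (a configuration choice documented in the segmentation
functions — the published procedure never excludes them either). Runs of
the averaged intensity profile above its global standard deviation are
merged across gaps < 0.5 s and kept if ≥ 2 s long (a bout must hold at
least one ~1.13 s stride). Whether the intensity profile should be |CWT| or
|CWT|² is not determined by the source description; |CWT| is implemented.

## Features

* Components are the **band-passed** stride slices, so means are near zero
  by construction and the Min/Max/RMS family measures oscillation
  amplitude/intensity.
* *Entropy* is the Shannon entropy of the normalized absolute-amplitude
  distribution, $-\sum p\log(p + 10^{-5})$ — the printed per-sample
  expression is not a scalar, and this reading preserves the "movement
  complexity" intent.
* The printed correlation-feature count is 7 while four components yield
  only six unordered pairs; the seventh is the lag-one autocorrelation of
  $\theta_x$ within the stride (a regularity measure). This is a
  documented guess.
* Spectra: every stride is mapped onto $n = \mathrm{round}(\bar T_{stride}
  \cdot F_s) = 68$ points (at 60 Hz) by linear interpolation across its own
  duration, giving every stride a comparable representation with
  ~0.9–1 Hz resolution (frequency axis $k/T_{stride}$). Up-sampling short
  strides follows the stated interpolation rule; down-sampling long ones is
  the symmetric reading of the "small loss of spectral resolution" remark.
* *Etot* is the magnitude sum $\sum_f |X_f|$ exactly as printed. *DHratio*
  and *binEnergy* are **power** (|X|², Parseval) fractions: magnitude-based
  fractions under-weight the dominant-harmonic lobe because un-windowed
  leakage tails add up linearly — a 1.2 Hz tone stride would get a
  "dominant" share of only 0.40, contradicting the quantity's purpose as a
  stride-regularity measure. *DHwidth* is the full width at half maximum,
  interpolated linearly, with the asymmetric interval `[lo, hi]` also used
  as the DHratio band.
* binEnergy bands are fixed at 0.5–2 (locomotor), 2–4, 4–8 (freeze band),
  8–12, 12–16, 16–20 Hz.
* Canonical ordering (`pigd_feature_names()`): time-domain features ×
  component, correlations, spectral features × component, band energies,
  then Tstride/Tstance/Tswing — 44 + 7 + 24 + 24 + 3 = 102, asserted at
  construction.

## Regression

Feature reduction is either correlation ranking (drop $|r| < 0.4$, keep the
top *N* by $|r|$; absolute value, because informative gait features
correlate *negatively* with severity) or PCA (loadings fitted on training
rows only). Scaling is z-score followed by min–max to [0, 1], all
statistics from training rows; test values are soft-clipped to
[−0.5, 1.5] so ordering survives. $\varepsilon$ defaults to one tenth of
the training-target SD.

The SVR dual is solved with `quadprog` (a tiny ridge keeps the
rank-deficient dual Hessian positive definite); the offset *b* is the exact
minimizer of the $\varepsilon$-insensitive loss given the dual weights — a
piecewise-linear 1-D problem — which is deterministic and stable where
KKT-based free-support-vector averaging is fragile.

Nested LOSO: every outer fold holds out one subject; the inner loop scores
every grid cell by inner-LOSO RMSE over the remaining $N-1$ subjects, ties
broken by grid order (kernel as listed, then smaller box constraint, then
smaller kernel scale). In the default leakage-safe mode, reduction and
scaling are recomputed inside every partition; `mode = "paper"` ranks
features once on all subjects first, matching the published processing
order, and is provided for comparability only. Final metrics are pooled
over the held-out predictions (each fold contributes one subject) and
reported on a [0, 1] scale set by the cohort's observed target range — an
affine reporting transform applied identically to truth and prediction, so
r is unaffected and RMSE is comparable to published magnitudes. Within each
fold the model never sees the held-out subject's target: predictions are
mapped back through the train-only inverse first.

The printed goodness-of-fit formulas contain two apparent typos (an
unsquared denominator term in r; MAE written against the target mean);
standard Pearson r and MAE = mean|ŷ − y| are implemented.

## The synthetic-data generator

No public recording of the original cohort exists, so every stage is
validated against `sim_config()`/`simulate_subject()`, an *angle-first*
generator: thigh pitch $\theta_x(t)$ is synthesized from the TUG phase
plan, then the gyroscope is its derivative plus bias and white noise, and
the accelerometer is the gravity projection through the angle plus a small
stride-locked bounce and noise. Ground-truth orientation, bouts, ICs and
FCs exist by construction.

Stated world (chosen once; none of these values is claimed to be measured):

| quantity | value | basis |
|---|---|---|
| stride time | 1.13 ± 0.21 s | pooled parkinsonian literature value |
| sampling | 60 Hz, ±2 g, ±245 dps ranges | sensor datasheet |
| pitch oscillation at severity 0 | 20° | plausible thigh swing; free parameter |
| severity effect | amplitude × (1 − 0.6·sev/20) | fixed sign, monotone |
| stride-time SD inflation | × (1 + sev/20) | fixed sign, monotone |
| subject traits | amplitude CV 8 %, stride-mean jitter 0.4·SD | people with equal PIGD walk differently |
| cohort severities | quantiles of N(7.3, 5.7) clipped to [0, 20] | published cohort PIGD OFF mean ± SD |
| OFF condition | severity + 1, effect gain 1.2 | published OFF−ON difference ≈ 1 |
| noise | accel 0.02 g, gyro 1 deg/s, bias 0.5 deg/s | plausible MEMS figures |
| FOG episodes | 1.5–3 s, amplitude × 0.1 plus 3–8 Hz tremble | standard freeze-band characterization (extrapolation) |
| FOG+ label | severity ≥ 8 | published FOG+/FOG− PIGD separation |

Walking bouts start at a stride-phase zero crossing and the trailing
partial stride is amplitude-tapered to zero, so gait initiation and
termination are continuous — without the taper, the mid-stride truncation
at the walk→turn junction injects a spurious pitch peak that no real
recording contains. Setting `stride_time_sd = 0` produces a fully
deterministic gait (exact periods, constant amplitude), which several
construction tests rely on.

What the generator does **not** emulate — and hence what a green test does
not establish: 3-D turning kinematics, foot-strike transients and
double-support timing (FCs are placed at the pitch trough, which is the
detector's definition, not an independent biomechanical event),
sensor-frame misalignment beyond the supplied rotation, arm/trunk
compensation, and any real relationship between signal morphology and the
clinical items behind the PIGD score. Regression results on synthetic
cohorts demonstrate *parameter recovery under the generator's assumptions*,
not clinical validity — the published patient-cohort numbers are not
reproducible without the patients.

The kernel-selection diagnostic deserves one honest caveat: on pipeline
cohorts the severity-linked features carry noise in X, and a large-scale
gaussian kernel is then a statistically equivalent quasi-linear competitor,
so the "fraction of folds choosing the linear kernel" is only meaningful on
a cleanly linear law (target generated linearly from the features), where
the suite asserts it.

## Known limitations

* Pure-R inner loops (IIR filtering, Kalman recursion) are fast enough for
  TUG-length recordings (~minutes for a 30-subject cohort end to end) but
  not for day-long free-living data.
* The full Algorithm-style grid (4 kernels × 7 × 7 log-spaced values) is
  supported but the test suite uses reduced grids to stay inside its time
  budget; grid contents are an explicit argument everywhere.
* `compare_groups` switches from exact to normal-approximation p-values at
  n = 25 or in the presence of ties.
* With 4 subjects the nested inner partitions contain 2 training rows,
  below the minimum for correlation ranking; practical cohorts need ≥ 5.
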