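# Feature dictionary

`pigd_feature_names()` returns the canonical 102-column order used by
`extract_features()` and the subject feature tables. Components:

| suffix | signal |
|---|---|
| `_ay` | acceleration along y (band-passed, g) |
| `_az` | acceleration along z (band-passed, g) |
| `_gx` | angular velocity about x (band-passed, deg/s) |
| `_th` | thigh pitch angle (Kalman estimate, band-passed, rad) |

## Time domain (11 x 4 = 44 columns, feature-major order)

| feature | definition |
|---|---|
| `Min`, `Max`, `Mean` | extrema and mean of the stride slice |
| `Std` | population standard deviation (divisor N) |
| `RMS` | root mean square |
| `Range` | Max - Min |
| `Entropy` | Shannon entropy of the normalized absolute-amplitude distribution, -sum p log(p + 1e-5) |
| `nPeaks` | strict local maxima higher than `Std` |
| `hPeaks` | mean height of those peaks (0 when none) |
| `vPeaks` | SD of those peak heights (0 when fewer than 2) |
| `Zc` | zero crossings per second of the mean-removed slice |

## Correlations (7 columns)

`Corr_ay_az`, `Corr_ay_gx`, `Corr_ay_th`, `Corr_az_gx`, `Corr_az_th`,
`Corr_gx_th`: Pearson correlations of the component pairs. `Corr_th_lag1`:
lag-one-sample autocorrelation of the pitch slice. Constant channels give 0
with a warning.

## Spectral (6 x 4 = 24 columns)

Every stride is linearly interpolated onto `round(1.13 * fs)` points (68 at
60 Hz) across its own duration; the frequency axis is `k / Tstride` (about
0.9 Hz resolution). The dominant harmonic (DH) is the largest amplitude in
0.5-20 Hz.

| feature | definition |
|---|---|
| `DHfrequency` | DH frequency (Hz) |
| `DHheight` | DH amplitude (unit-sinusoid scale) |
| `DHwidth` | full width at half maximum of the DH lobe (Hz) |
| `Etot` | sum of spectral magnitudes above DC |
| `DHratio` | power fraction (Parseval) inside the FWHM interval, in [0, 1] |
| `sEntropy` | Shannon entropy of the normalized magnitude spectrum |

## Band energies (6 x 4 = 24 columns)

`binEnergy1` .. `binEnergy6`: power fractions in 0.5-2 (locomotor), 2-4,
4-8 (freeze band), 8-12, 12-16, 16-20 Hz; each in [0, 1].

## Temporal (3 columns)

`Tstride = IC_{i+1} - IC_i`, `Tstance = FC_i - IC_i`,
`Tswing = IC_{i+1} - FC_i` (seconds); `Tstride = Tstance + Tswing` exactly.

Subject tables from `aggregate_subject()` / `cohort_features()` prepend
`subject_id`, `condition`, `fog_status`, `pigd`, `n_strides` and hold the
arithmetic mean over strides for every feature.
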