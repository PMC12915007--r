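---
title: "Methods: oscillatory source power, decoding and gaze metrics in a dual-task design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillatory source power, decoding and gaze metrics in a dual-task design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`oscidual` implements the analysis chain of a dual-task M/EEG +
eye-tracking experiment with a 2 (visuo-spatial workload: LW, HW) by 3
(speech valence: LV, NV, HV) within-subject design, together with a
synthetic cohort generator that plants known condition effects so that
every stage can be validated end to end. This vignette is the package's
account of the underlying models, the tunable parameters, and the design
choices made where several defensible options existed.

## The synthetic cohort

Real MEG source analysis requires an anatomical forward model (MRI
segmentation, boundary-element conductor, co-registration). None of that
machinery carries statistical content for the algorithms implemented
here: beamforming and minimum-norm inversion only need a *known* gain
matrix. The generator therefore works on an abstract spherical geometry:

* **Source grid.** Vertices of a recursively subdivided icosahedron
  projected to the unit sphere (`subdivide_icosahedron()`, level 2 by
  default: 162 vertices, the same construction that yields 10,242
  vertices per hemisphere at level 5 in full-resolution cortical grids).
  Mesh edges define the adjacency used for spatial clustering.
* **Lead field.** Each source's sensor loading is a Gaussian-kernel
  mixture (kernel width `smoothness = 0.35` in chordal distance) of
  i.i.d. sensor loadings over its grid neighbourhood, then normalized to
  unit column norm. Neighbouring sources thus project similarly —
  the property that makes localization "to the true vertex or a
  neighbour" the right success criterion — without any head geometry.
  Sensor noise has a diagonal-plus-low-rank covariance, the analogue of
  an empty-room measurement.
* **Source signals.** Per source, a `1/f^χ` background (exponent drawn
  uniformly from `exponent_range = c(0.8, 1.6)` per subject and vertex)
  plus narrowband alpha (8–12 Hz), beta (15–25 Hz) and gamma (30–42 Hz)
  oscillations realized as band-pass-filtered Gaussian noise: the
  amplitude profile of a 4th-order zero-phase Butterworth band-pass is
  applied to a white complex spectrum and inverted in one FFT. Filtered
  noise, not sinusoids, is used deliberately so that spectra carry
  realistic peak widths for the aperiodic/periodic decomposition.
  Oscillation amplitude defaults to 1 background SD per band
  (`osc_snr`).
* **Planted effects.** An `effect_spec()` multiplies the variance of one
  band's oscillation inside a vertex patch by a per-condition gain. The
  default cohort (`default_effects()`, gain 1.5) plants a parietal-style
  beta increase for emotional speech, a workload gamma increase with a
  concomitant beta decrease, and a cross-over gamma interaction
  (LV > HV under LW reversing to LV < HV under HW). Baseline blocks use
  all gains 1; the empty-room block contains sensor noise only.
* **Behavioural streams.** Pupil diameter = mean + slow sinusoidal
  drift + white noise + sharp-onset exponentially decaying transients at
  Poisson times (the discontinuities the IPA counts), with NaN gaps at
  blinks; gaze positions are piecewise-constant fixation sequences;
  telemetry channels are mean-reverting AR(1) processes. High workload
  raises pupil diameter (+0.3 mm), tightens fixation scatter (×0.6,
  "visual tunnelling"), lowers blink rate (×0.7), raises the
  discontinuity rate (×1.5), and degrades driving (higher volatility,
  lane noise, brake use, violation rate). These magnitudes are fixed
  generator defaults chosen as plausible desk-scale values, not fitted
  quantities.

Everything regenerates bit-identically from `(config, seed)`; child
seeds are derived once from the master seed so that disabling one stream
does not shift another stream's draws within a block.

What the generator does **not** emulate: ocular/cardiac artifacts,
sensor drift, head movement, heteroscedastic measurement noise,
inter-subject anatomical variability, or any correlation between the
neural and behavioural streams beyond the shared condition labels.
Passing recovery tests on this cohort therefore demonstrates algorithmic
correctness and statistical calibration — not robustness to real-world
artifact structure.

## Oscillatory source power (main-effects route)

Continuous blocks are cut into non-overlapping 5-s epochs, amplitude
rejection (absolute channel maximum; peak-to-peak available) drops noisy
epochs, and trial counts are equalized across conditions by a greedy
rule that removes, at each step, the epoch whose removal most reduces
the summed pairwise difference of matched-rank onset times across
conditions (ties drop the later onset — deterministic audits).

Cross-spectral densities come from a complex Morlet decomposition
(3 cycles, 1–42 Hz), averaging coefficient outer products over epochs
and over the time points outside the wavelet half-support. Sensor data
are pre-whitened with the empty-room covariance (Ledoit–Wolf-shrunk,
eigenvalue-truncated). DICS spatial filters
`w_v = (l_v' S_r^{-1} l_v)^{-1} l_v' S_r^{-1}` use the real part of the
CSD with 5% diagonal loading — a standard stabilizing value on small
grids; filters satisfy unit gain `w_v l_v = 1` exactly. One common
filter set per subject is computed from the mean broadband CSD over all
condition and baseline blocks, so that condition contrasts cannot be
driven by condition-specific filters.

Per-vertex spectra are parameterized in log10-power space: a robust line
fit over log frequency (refit on the points closest to the initial
line), iterative Gaussian peak extraction from the residual (peak width
limits 2–6 Hz, at most 7 peaks, absolute threshold 0, relative threshold
1 residual SD, knee-less "fixed" mode), and a final aperiodic refit on
the peak-subtracted spectrum. The aperiodic component is subtracted **in
linear space and without clipping**: clipping negative residuals would
bias condition contrasts. One fit per vertex and block is performed (the
fit is the expensive primitive; `max_peaks = 3` there, since source
spectra carry at most the three planted bands).

Individual band peaks are detected per subject from baseline sensor
spectra (multitaper, 2 Hz bandwidth): per band, the tallest fitted
Gaussian inside the cutoff range, averaged across sensors; a band
without a peak falls back to the band midpoint and is flagged. Band
power is the mean of the residual spectrum in a closed 2-Hz window
around the individual peak, and the final per-vertex quantity is the
baseline-relative change `(P_cond − P_base)/|P_base|`.

## Cluster permutation statistics

Per vertex, a classical two-factor within-subject ANOVA decomposes the
2 × 3 cells; each effect's F is its mean square over its
effect-by-subject interaction mean square, with dfs (1, n−1) for
workload and (2, 2(n−1)) for valence and the interaction. The
implementation is a vectorized sums-of-squares decomposition; the test
suite pins it to an explicit brute-force oracle and to
`stats::aov(Error())` strata at 1e-8.

Cluster inference thresholds the F map at the parametric
`qf(0.95, df1, df2)` quantile, groups suprathreshold vertices by mesh
adjacency, and compares each observed cluster's mass (sum of F) against
the permutation null of **maximum** cluster masses. The default
permutation scheme independently re-labels all six condition cells
within each subject (full 6! shuffles); a factor-restricted scheme
(shuffling only the tested factor's levels within the other factor) is
available via `scheme = "factor"`. P-values use the `(1 + k)/(1 + N)`
estimator, so no cluster can receive p = 0. Post-hoc contrasts average
power over significant-cluster vertices and use Wilcoxon signed-rank
tests (exact for n ≤ 12 without ties, otherwise normal approximation
with tie and continuity corrections) with Benjamini–Hochberg FDR, plus
percentile bootstrap means/CIs (Bonferroni-scaled tails when several
intervals are shown together).

Calibration (type-I error, power) is measured on dataset-level cohorts
(`simulate_factorial_dataset()`: additive subject offsets, i.i.d. cell
noise, planted patch mean shifts of 1 within-cell SD) because the test's
contract input is the subjects × conditions × vertices array; sensor-level
simulation adds runtime, not statistical content, at this layer.

## Multiclass decoding (interaction route)

The decoding route band-passes the raw sensor blocks at 30–42 Hz
(zero-phase windowed FIR, ~2 Hz transition, ≥40 dB stop-band), cuts 2-s
epochs, and equalizes the four workload-by-valence classes (LW/LV,
LW/HV, HW/LV, HW/HV). The multiclass CSP whitens the Ledoit–Wolf class
covariances by the grand-average covariance and jointly diagonalizes
them with Jacobi rotations (compiled kernel); components are ranked by
the variance across classes of their projected log-variances — zero for
exchangeable classes — and the top 4 retained. A one-vs-rest variant
sits behind `method = "ovr"`. Features are per-epoch log-variances of
the filtered time courses; the classifier is an LDA with Ledoit–Wolf
within-class covariance and least-squares (normal-equation) weights.

Evaluation uses repeated stratified cross-validation (10 folds × 3
repetitions = 30 partitions by default), macro-averaged F1, a pooled
confusion matrix, and a percentile bootstrap CI over the fold scores.
With four balanced classes and label-independent data the macro F1
concentrates at the 0.25 chance level — the package's primary data-free
calibration target.

Decoding weights are made interpretable by the forward-model
transformation `A = Σ W' (W Σ W')^{-1}` with Σ the training-fold sensor
covariance, averaged across folds, then localized by a minimum-norm
operator `M = R L' (L R L' + λ² I)^{-1}` in whitened space with a
depth-weighted prior `R_vv ∝ ||l_v||^{-2·0.8}`, trace-scaled so that
`λ² = 1/SNR²` acts on a unit-signal scale: SNR 3 for pattern
localization, SNR 1 for source band power, conventional values for
evoked-scale versus single-trial-scale estimates. The synthetic forward
model has scalar (fixed-orientation) sources; the loose-orientation
machinery (tangential components down-weighted by 0.2, estimates
combined by their norm) is implemented for three-orientation gain
matrices but not exercised by default. No noise normalization (dSPM-like
variants) is applied. Subject maps are averaged with weights
proportional to each subject's decoding F1 and min-max rescaled to
[0, 1]; the ROI for condition contrasts is the set of vertices above the
90th percentile of the grand-average pattern magnitude. Pattern
averaging across folds happens in sensor space, before source
projection.

## Gaze and driving measures

Pupil preprocessing is fixed-order: cubic-spline interpolation of blink
gaps (50 ms padding, gaps over 500 ms stay masked; boundary gaps take
the nearest valid value and are flagged), a centred 20-ms rolling
median, then masking (not clamping) of samples outside 1–9 mm.

The IPA counts abrupt discontinuities as thresholded modulus maxima of
the level-2 Symlet-16 wavelet detail coefficients, with the hard
universal threshold `λ = σ̂ √(2 ln n)` and `σ̂ = MAD/0.6745`, expressed
as events per second of valid signal; masked runs split the computation
and counts are summed. Two numerical guards keep the estimator sane:
detail coefficients inside the filter support at segment boundaries are
excluded (symmetric-extension kinks), and λ is floored at 1e-8 of the
signal range so that noiseless smooth signals yield exactly zero events.
The 20-ms median filter leaves mildly heavy-tailed coefficients, which
produces a small false-positive floor (~0.4 events/s at the default
noise level); the injection-recovery tests bound the resulting bias.

Gaze dispersion is the duration-weighted RMS distance of fixations from
the duration-weighted centroid (a single fixation yields 0 with a flag);
blink rate is count over block duration; pupil dilation is the median
diameter during fixations. All gaze measures are baseline-corrected by
subtracting the preceding baseline block's value.

Driving performance uses five measures per block — RMSSD of acceleration
and of steering rate, mean brake actuation, mean absolute lane deviation
excluding ±2 s around each lane change, and the count of radar/collision
violations — min-max normalized within subject across that subject's six
blocks (matching the within-subject statistics downstream), averaged,
inverted so higher is better, and min-max rescaled once more. A measure
constant across blocks contributes 0 with a flag rather than propagating
NaN. Steering RMSSD operates on the angular-rate channel.

## Numerical choices and degenerate inputs

* DPSS tapers come from the symmetric tridiagonal eigenproblem, cached
  per (length, bandwidth); taper count `floor(2NW) − 1`. PSD scaling is
  Parseval-consistent (integral ≈ variance, verified to 10%).
* The peak extractor refuses peaks below a 1e-6 log-power floor so
  machine-precision ripples on noiseless spectra are not "peaks".
* `rm_anova_F` detects exact ties across conditions with a relative
  sums-of-squares tolerance; true zero-error-with-effect cells give
  F = +∞ with a flag rather than NaN.
* Degenerate inputs error with actionable messages: all epochs rejected
  names the block; a uniform pattern map makes the percentile ROI
  ill-defined (full-vertex fallback behind `uniform = "all"`); relative
  change with a zero baseline lists the offending vertices.

## Problem sizes

The package's own validation runs at desk scale, chosen to exercise the
full pipelines in minutes: 162-vertex grids, 24–64 sensors, 100 Hz
sampling, 30–120 s blocks, 6–12 subjects per cohort; the cluster-test
calibration uses 50 null and 20 planted cohorts at 12 subjects × 162
vertices with 200 permutations; the cross-over recovery uses 20 cohorts
of 8 subjects with 5-fold cross-validation; the chance-level target uses
20 synthetic datasets of 400 epochs × 64 channels under 10-fold × 3
cross-validation. Production analyses would raise permutations to 5,000
and bootstrap iterations to 5,000 (the defaults of
`permutation_cluster_test()` and `analysis_config()`).

## Known limitations

* The forward model is spherical and single-compartment; localization
  accuracy statements transfer to real anatomy only qualitatively.
* One adjacency graph (no hemisphere split), so no inter-hemispheric
  bookkeeping.
* The aperiodic fitter is knee-less; spectra with a clear knee need a
  different fit range.
* Group inference uses the permutation/bootstrap machinery only; no
  mixed-effects models are fitted.
* The IPA false-positive floor noted above makes absolute rates
  conservative at very low true rates; between-condition contrasts are
  unaffected.
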