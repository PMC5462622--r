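---
title: "Methods: traveling-wave tuning, tactile psychophysics and MRS statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: traveling-wave tuning, tactile psychophysics and MRS statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatotune)
```

This vignette documents the models implemented by `somatotune`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data generators do and do not emulate. It
states no empirical claim that the package's tests and acceptance script
do not themselves compute.

## 1. Traveling-wave analysis and the cortical tuning metric

### Model

The digit-cycling task moves an activity block continuously through the
digits: 8 s per digit, a 32 s cycle over digits 2–5, repeated 8 times,
sampled at TR = 1.5 s (all configurable via `task_design()`). The lag-`L`
reference model is a boxcar (8 s on, 24 s off per cycle) circularly
shifted by `L` on a 0.1 s grid, convolved with a gamma HRF and sampled at
the TR (`build_reference_model()`). A voxel's *tuning profile* is the
Pearson correlation of its time series with this model at every lag on a
grid spanning the cycle (`compute_tuning_profile()`); the profile peaks at
the voxel's preferred point in the movement cycle, and its width reflects
how selective the voxel is.

The profile is then summarized by a least-squares sinusoid
`y = a sin(ωx − φ) + B` (`fit_sinusoid()`). The fitted period (in seconds
of lag) tracks the width of the response bump; the **cortical tuning
metric** is `1/mean(period)` over an FDR-defined ROI (`define_roi()`,
`tuning_metric()`). Sharper tuning, shorter period, larger metric.

### Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| TR | 1.5 | s | standard high-resolution EPI protocol for this task |
| block / cycle / cycles | 8 / 32 / 8 | s, s, count | the validated hand-digit paradigm |
| HRF | gamma, shape 6, scale 0.9 | – , s | single-gamma peaking ~4.5 s; the source method says only "gamma-convolved", so the kernel is configurable |
| lag grid | step = TR | s | avoids interpolating the data; the boxcar is built on a 0.1 s grid so the cycle need not be a multiple of the TR (32 s / 1.5 s is not) |
| period bounds | [2·lag step, 2·cycle] | s | identifiability floor (Nyquist on the lag grid) and a generous ceiling |
| ROI α | 0.01 | – | FDR level on the Fisher-transformed amplitude map |

### Numerical choices

**Profiled least squares instead of 4-parameter multi-start.** For fixed ω
the sinusoid is linear in `(a cos φ, −a sin φ, B)`, so the fit solves those
three exactly and searches only over the period (coarse log grid, then
bounded 1-D refinement). This computes the same global least-squares
estimate a multi-start nonlinear solver targets, without convergence
failures; `converged = FALSE` can then only arise from non-finite input.
A profile with essentially zero variance is flagged `degenerate` (its
amplitude is ~0 and its period meaningless); such voxels are excluded from
the maps, and the exclusion count is reported.

**Circular recentering.** The tuning profile is periodic in the cycle:
lag 0 and lag 32 s name the same moment of the movement. A free-period
sinusoid, however, is not periodic in the fitting window, and fitting a
profile whose peak sits at the window cut splits the bump across the edges
— empirically this inflates the fitted period severely for sharply tuned
voxels and *inverts* the expected width→period relationship. The fit
therefore re-cuts the circular lag coordinate so the peak lies mid-axis
(an exact re-parameterization for cycle-periodic profiles) and maps the
fitted phase back. With recentering, simulations show a strong monotone
coupling between ground-truth tuning width and the fitted period
(roughly 26 s at width 0.4 up to 34 s at width 1.3 under the default
noise level); the acceptance suite checks this monotonicity. Plain
`lags`/`r` lists without a `cycle_s` field are fitted as-is, which keeps
brute-force grid-search comparisons well defined.

**Aggregation order.** The metric averages the period over the ROI and
inverts (`1/mean(period)`), following the written description of the
method; the figure-level description of the same quantity reads as a
per-voxel inverse, so `mean(1/period)` is available behind
`aggregate = "mean_inverse"`. For homogeneous ROIs the two agree; for
heterogeneous ROIs the default is the documented one.

**p values on time-series correlations.** ROI definition applies the
Fisher transform with variance `1/(n−3)` to sinusoid *amplitudes*, as in
the source procedure. fMRI time series are autocorrelated, so these are
not calibrated p values for single-voxel inference — they are a
thresholding device inside an FDR procedure; the synthetic AR(1) noise
option exists precisely to let users probe this caveat.

**Forward/backward combination.** Amplitude and period are invariant to
reversing the lag axis, so maps from backward runs are directly averaged
with forward ones; only voxels converged in both contribute.

## 2. Psychometric fitting and the JND

Per-ISI proportions of "middle-finger-first" responses are fit with a
two-parameter logistic by *unweighted least squares* — the paper-faithful
choice, consistent with reporting an r² for the fit — with a binomial
maximum-likelihood option (`method = "ml"`) for users who prefer it. No
lapse parameter is fitted (the simulator can generate lapses to
stress-test). Fits with r² ≤ 0.4 are flagged as rejected. The JND is
computed analytically: the p-quantile of the logistic is
`μ + s·ln(p/(1−p))`, so half the 25%–75% span is `s·ln 3` exactly,
independent of `μ` — relabeling which finger counts as "first" flips `μ`
and leaves the JND unchanged, which is why either response-coding
convention yields identical acuity estimates.

At 16 trials per ISI the sampling spread of the JND estimate is a
property of the data, not of the optimizer: the test suite checks the
optimizer against a dense grid-search fit per replicate and takes the
recovery envelope from that oracle's own error distribution.

## 3. MRS quality control and tissue correction

Exclusion rules are applied record-wise and strictly
(`crlb > 50`, `fwhm_hz > 15`, `snr < 40`; boundary values are kept), with
a strict mode keeping only CRLB < 30%. The printed correction expressions
in this literature are typographically ambiguous; `somatotune` implements
standard partial-volume scaling — division by the relevant tissue
fraction — because multiplying would *shrink* estimates from voxels with
less tissue, the opposite of a partial-volume correction:

- GABA/Glu: `corrected = absolute / (GM/(GM+WM+CSF))`, requiring GM > 0;
- total creatine: `(Cr+PCr) / ((GM+WM)/(GM+WM+CSF))`, factor ≥ 1 always.

The GM denominator uses the full voxel (`GM+WM+CSF`), matching the symbol
list of the printed formula, rather than the brain-only alternative
(`GM+WM`); both are simple rescalings and leave creatine ratios' rank
order unchanged for fixed tissue composition. Raw (non-ratio) corrected
concentrations are available via `mrs_ratios(..., ratio = FALSE)`.

## 4. Statistics

- **Pearson/partial correlations**: t construction, two-tailed, on
  `n−2` / `n−3` df. The partial correlation equals the residual-regression
  construction to machine precision (tested).
- **Hittner's test**: the back-transformed-average-z modification of the
  Dunn–Clark statistic for two dependent correlations sharing a variable.
  The predictor–predictor correlation `r_yz` is a required argument — it
  cannot be inferred from the two printed correlations. Both tail
  conventions are returned because published values in this design match
  the one-tailed normal tail even under blanket "two-tailed" statements;
  nothing is hidden from the user.
- **Conjunction/omnibus**: the compound null is rejected only if
  `max(predicted p) < α` and `min(unpredicted p) ≥ α`. The verdict is
  monotone in the predicted p values (tested).
- **Mediation**: OLS path decomposition; percentile bootstrap (5000 case
  resamples by default, seeded and bit-reproducible) for `a·b`; Sobel
  `Z = ab/√(b²SE_a² + a²SE_b²)` with a two-tailed normal p; κ² as the
  indirect effect relative to its maximum attainable magnitude given the
  observed variances and the positive-semidefiniteness of the covariance
  matrix (the constrained-maximum construction; its known caveats —
  non-monotonicity in |ab| under some configurations — apply). `P_M` is
  flagged unstable when the total effect is small relative to its SE,
  since the ratio then explodes.
- **ICC(A,1)**: single-measures two-way random-effects absolute-agreement
  ICC from the ANOVA decomposition, with the F-based CI. Absolute
  agreement penalizes session offsets (tested), unlike the consistency
  form.

## 5. What the simulators emulate — and what they do not

`simulate_fmri_run()` builds voxel signals as wrapped-Gaussian mixtures of
HRF-convolved digit regressors (peak-normalized so the zero-width limit is
exactly the preferred digit's reference model) plus Gaussian, optionally
AR(1), noise. It does **not** simulate head motion, physiological noise,
field inhomogeneity or spatial autocorrelation; a green traveling-wave
test therefore establishes the correctness of the analysis chain, not its
robustness to artifacts that preprocessing is assumed to have handled.

`simulate_toj_trials()` is a stationary logistic observer with an optional
symmetric lapse (`λ/2 + (1−λ)·logistic`, the standard psychophysics
convention; default λ = 0) — no learning, fatigue or serial dependence.

`simulate_cohort()` draws (X, M, Y) = (GABA:Cr, tuning, JND) from two
linear structural equations `M = aX + e_M`, `Y = c′X + bM + e_Y` with
X ~ N(0,1), then maps them affinely onto realistic measurement scales
(GABA:Cr ≈ 0.25, tuning ≈ 0.06 s⁻¹, JND ≈ 90 ms); affine maps leave all
correlation-based statistics untouched. The implied covariance has a
closed form (`implied_covariance()`) used as the generator's oracle. The
literature states no generative model for inter-subject variability: this
generator is an explicit stand-in, and defaults (a = 0.7, b = −0.6,
c′ = 0, n = 22) encode the qualitative structure reported there —
complete mediation with correlations in the 0.6–0.7 range — not a claim
about any real cohort.

In raw-level mode each subject's latent tuning is mapped monotonically to
a voxel tuning width (cubically steepened so cohorts span the width range
where the fitted period is most sensitive, calibrated once by simulation)
and the latent JND to an observer slope (`slope = JND/ln 3`, exact by the
closed form). `simulate_mrs_table()` emulates an LCModel-style output
table at the spectrum level: each of `n` spectra contributes GABA, Glu,
Cr and PCr rows sharing linewidth, SNR and tissue fractions, and QC
failures are injected into exactly `round(n·fraction)` spectra.

## 6. Degenerate inputs, tie-breaks, tolerances

- Constant voxel time series: flagged profile, excluded downstream.
- Empty ROI: `tuning_metric()` refuses with an error rather than return a
  vacuous number.
- Tissue fractions must sum to 1 within 1e-6; GM = 0 (or GM+WM = 0) makes
  the respective correction undefined and errors.
- All-0/all-1 psychometric proportions: non-identifiable, flagged, no JND.
- Every generator and the bootstrap take explicit integer seeds; the
  pipeline derives per-stage seeds deterministically from the global seed
  (kept below 2³¹), and repeated runs are byte-identical.
- CSV output uses 17 significant digits so numeric tables round-trip
  bit-for-bit; NIfTI I/O (a minimal NIfTI-1 float reader/writer, since no
  NIfTI package is available in the target environment) round-trips
  exactly.

## 7. Known limitations

- No preprocessing: motion correction, brain extraction, temporal
  filtering and tissue segmentation are assumed done upstream; only a
  simple high-pass for synthetic data would be in scope and none is
  applied by default.
- The Hittner, Sobel and correlation p values assume approximate
  normality; the package logs nothing about distributional checks beyond
  what the user computes.
- κ² and `P_M` are reported because they are the field's reported effect
  sizes, with their caveats documented rather than resolved.
- The NIfTI reader supports plain scalar images (the formats this
  pipeline writes), not the full standard.
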