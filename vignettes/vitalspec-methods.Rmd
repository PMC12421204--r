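---
title: "Spectral feature engineering and nu-SVC mortality prediction for ICU vital signs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral feature engineering and nu-SVC mortality prediction for ICU vital signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bedside monitors stream vital signs — arterial oxygen saturation (SaO2),
heart rate, respiration rate, and estimated ST-segment levels from three ECG
leads — continuously from the moment a patient enters the ICU. Summary
statistics of these traces (worst value, mean, SD) are what most deployed
mortality scores consume, but they discard the *dynamics*: a patient whose
SaO2 dipped hard early and then stabilized looks, through the lens of min and
SD, sicker than a patient who fluctuates moderately but never settles, even
though persistent instability is the stronger adverse signal.

`vitalspec` implements a three-stage pipeline that keeps those dynamics:

1. **Decomposition.** Each regular vital-sign series `v_t` from the first
   24 hours is decomposed four ways: one-sided FFT magnitude spectrum, power
   spectral density (PSD), normalized autocorrelation sequence, and
   continuous wavelet transform (CWT) scalograms under Morlet, complex
   Morlet, and Mexican-hat mother wavelets.
2. **Feature extraction.** Each spectrum (and each configured scalogram
   scale row) yields *relative extrema* (position and amplitude of the top-n
   local maxima/minima) and *power-in-band* features (sums over consecutive
   segments of the spectrum); the raw series yields 10 summary statistics and
   *moving-window sudden-change* features (samples outside mean ± 3 SD of a
   sliding window).
3. **Classification.** The feature matrix is median-imputed and z-scored
   per training fold, pruned by an L1-penalized sparse linear classifier,
   and classified by a class-weighted nu-SVC with Platt-calibrated
   probabilities, evaluated by stratified 5-fold cross-validation (AUC).

## Model and conventions

**Regular grid.** Series live on a half-open window `[0, 86400)` s at a
300 s cadence (288 samples) — the cadence of periodic eICU-style monitor
extracts. Irregular samples snap to the nearest grid point (last wins);
internal gaps of at most 30 min are linearly interpolated, longer gaps stay
missing. Spectral transforms require complete series and run on a
linear-interpolation + edge-hold imputation; statistics and moving windows
see the raw missingness.

**Spectra.** The series mean is removed before FFT/PSD — the DC term
otherwise dominates every band feature. The PSD is the periodogram
normalized so the folded two-sided power equals the biased sample variance
(`|X_k|^2 / N^2`, interior bins doubled one-sided); this is exactly the
discrete transform of the biased autocovariance sequence, which is how the
unit tests cross-check it. Autocorrelation uses the biased (divide-by-N)
estimator normalized to `r(0) = 1`, lags 0–40 by default. The CWT is
computed by direct FFT-based convolution with the sampled, scale-normalized
mother wavelet and zero extension beyond the window; complex families are
reduced to `|W(a, b)|`. The default scale grid is 32 log-spaced scales in
[1, 64] samples (5 min to several hours at 300 s), with features taken from
4 log-spaced rows of that grid — the scalogram-to-feature reduction is not
fixed by the underlying method, so treating each configured scale row as a
spectrum is this package's choice, and it makes band 1 of a scalogram row
the *earliest time segment* at that scale (band features on FFT/PSD/AC
spectra remain frequency/lag bands).

**Relative extrema.** A point is a relative maximum iff its ordinate is ≥
every ordinate within abscissa distance ε (default 3 bins). Boundary points
compete only against their one-sided neighborhood, so a global maximum at
the spectrum edge is never dropped. Tied candidates within ε keep the
smallest abscissa; the top n = 5 per mode are reported, missing-padded when
fewer exist. Missing slots are left to the model-stage imputation — the
matrix preserves its missingness mask.

**Moving windows.** Windows of k = 12 samples (1 h), stride 1, flag samples
strictly outside mean ± 3 SD, where mean and SD are computed from the k
observations *including* the candidate and SD uses the population
(denominator k) convention. That convention matters: the deviation of a
single outlier measured against a self-inclusive SD is bounded by
`(k-1)/sqrt(k)` ≈ 3.18 at k = 12, so with a denominator of k−1 a 3-SD rule
could barely ever fire; with denominator k it reliably detects the deep
desaturation events the generator plants. A zero-SD window flags nothing.

**Selection and classifier.** "Sparse linear selection followed by a
nu-margin classifier" is realized as lasso-penalized, class-weighted
logistic regression (glmnet) for selection — the closest well-posed convex
sparse linear classifier available — with the penalty chosen by internal
stratified 5-fold CV (or fixed via `C_sel = 1/lambda`). When more than 500
features survive, a univariate weighted-difference screen keeps the
strongest 500 before the lasso (sure-independence-style, fitted on training
folds only). The final classifier is a nu-SVC (libsvm via e1071), RBF
kernel, `gamma = 1/(m * mean feature variance)`, nu = 0.5 by default; nu
simultaneously upper-bounds the margin-error fraction and lower-bounds the
support-vector fraction, which the tests verify on every fit via the KKT
multipliers (margin errors are the bound-active multipliers — the decision
values themselves are blurred by solver tolerance). libsvm ignores per-class
weights in the nu formulation, so class weights `w_i = n/(2 n_i)` are
applied by integer replication of minority rows before the fit. Probabilities
come from a Platt-style sigmoid fitted on the training decision values with
prior-corrected targets; infeasible nu (`nu >= 2 min(n0, n1)/n`) is reported
as a fit error with the feasible bound.

**No leakage.** Imputation medians, standardization parameters, the
screening statistic, the lasso, and the SVC are all fitted strictly inside
training folds and applied verbatim to the held-out fold.

## The synthetic cohort generator

No credentialed clinical data ship with the package; the generator emulates
the *structure* of an eICU-style heart-failure extract so the pipeline is
testable end to end:

* 24 h × 300 s grid, 5.66% positive (expired) prevalence, per-vital
  patient-level missingness {SaO2 0.73%, heart rate 0.02%, respiration
  6.04%, ST1 48.67%, ST2 47.11%, ST3 50.62%} plus 2% within-series dropout;
  baselines at clinically representative means (SaO2 96.4%, HR 88.2 bpm,
  respiration 21.4/min, ST ≈ 1), clipped to physiological ranges
  (SaO2 ∈ [0, 100], HR ∈ [0, 300], ...).
* Broadband noise is AR(1) with ρ = 0.8 — bedside vitals are autocorrelated,
  and white noise would make the autocorrelation features degenerate.
* **Survivor archetype**: an early broadband fluctuation (3× noise SD, with
  occasional deep early SaO2 drops) that stabilizes at ≈ 840 min
  (SD 120 min). **Deceased archetype**: persistent band-limited oscillation
  (0.10–0.15 cycles/sample, 2× noise SD) on SaO2/HR/respiration, sudden
  SaO2 drops at Poisson times (3/day, depth 12–25 local SDs), optional
  drift. Every planted event is logged so detector recovery is checkable.

The **moment-matched variant** is a sharper harness for the claim that
spectral features carry information summary statistics cannot: both classes
are baseline + shared AR(1) noise + a phase-randomized narrowband
oscillation at *equal* amplitude (0.5× noise SD) and *equal* bandwidth, only
the band's center differs by class (0.10–0.15 vs 0.18–0.23 cycles/sample),
and every series is then rescaled to exactly the target mean and SD. Means
and SDs therefore carry zero class signal by construction. The residual
channel through extreme-value statistics (a higher-frequency band raises the
level-crossing rate and hence the expected max) is deliberately suppressed
by keeping the oscillation at half the broadband SD, so the extremes are
dominated by the class-free broadband component; the band centers and the
0.5 amplitude ratio were fixed by this argument at design time. This variant
defaults to the three high-coverage vitals (SaO2, HR, respiration): it
isolates the spectral-vs-statistical contrast and has no use for the ~50%
patient-level ST missingness.

What passing on these cohorts does **not** show: real ICU traces have
nonstationary artifacts, sensor dropouts correlated with care events, and
cross-vital dependence the generator does not model; results here validate
the machinery, not clinical performance.

## Problem sizes and numerical choices

The test suite exercises the heavy end-to-end properties at the sizes the
statistical claims need: moment-matched cohorts of n = 2000 at 5.66%
prevalence over 20 seeds for the spectral-vs-statistical contrast,
n = 1000 over 10 seeds for importance concentration, 10^6 pooled Gaussian
samples for the 3-SD null calibration, 1,000 random instances per
brute-force oracle comparison. The acceptance script reports the same
quantities at n = 1200/2000 with 5 matched-moments seeds.

Numerical details worth knowing: FFT-based convolution pads to a
2-3-5-smooth length; wavelet kernels are truncated where the Gaussian
envelope falls below ~1e-8; extrema ties resolve to the smaller abscissa;
fold assignment deals shuffled class members round-robin so fold class
counts differ by at most one; all randomness flows from explicit seeds and
identical (data, config, seed) reruns are bit-identical on one machine. An
empty lasso selection falls back to the 20 largest-|coefficient| features at
the weakest path penalty, with a warning.

## Known limitations

* The CWT reduces complex coefficients to modulus before feature
  extraction; phase information is discarded by design.
* Scalogram features depend on the configured scale rows; there is no
  automated per-cohort tuning of ε, n, L, or k.
* The selection surrogate is logistic-loss, not hinge-loss; coefficients
  (and hence the importance table) can differ from a hinge-based selector on
  near-separable data.
* Probability calibration is a two-parameter sigmoid; it is monotone in the
  decision value but not guaranteed calibrated under covariate shift.
* With an RBF kernel, decision values for points far from all training data
  revert toward a constant, so extrapolated probabilities drift to the
  class-prior side rather than to certainty.
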