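---
title: "Detecting alcohol-affected drivers from single-lead ECG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alcohol-affected drivers from single-lead ECG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgddd)
```

## The problem

Alcohol measurably alters the electrocardiogram: the P wave flattens and
its duration becomes more variable, the R and S deflections grow, and
the heart rate rises.  `ecgddd` implements a complete pipeline that
turns these effects into a binary classifier ("normal" vs "drunk"):
synthetic two-class ECG cohorts, Pan-Tompkins beat detection, P/QRS/T
delineation, a fixed 10-dimensional feature vector, correlation-weighted
composite kernels, a dual SVM solver, and 10-fold cross-validated
accuracy/sensitivity/specificity reporting.

The class contrast the package injects and recovers is (drunk relative
to normal): P peak −11.21%, R peak +19.54%, S peak +8.14%, R-R interval
−8.43%, maximal P-wave duration (Pmax) +9.07%, and P-wave dispersion
(Pd, the within-record range of P durations) +23.77%.

## The synthetic cohort generator

No public ECG corpus pairs sober and intoxicated recordings of the same
subjects, so the package generates its own study.  Each heartbeat is a
sum of five Gaussian bumps, one per wave.  A Gaussian template is not a
cardiological model; it is chosen because every downstream measurement
then has a closed form (the 10%-threshold duration of a Gaussian of
width $\sigma$ is exactly $2\sigma\sqrt{2\ln 10}$), which makes the
whole measurement chain testable against ground truth.

Default normal morphology (lead-II-like): P 0.15 mV at −160 ms from the
R peak ($\sigma$ 22 ms), Q −0.10 mV at −30 ms, R 1.0 mV ($\sigma$
10 ms), S −0.25 mV at +30 ms, T 0.35 mV at +300 ms ($\sigma$ 45 ms).
The P width jitters uniformly by ±6 ms from beat to beat; this jitter
is what gives a record nonzero P-wave dispersion.  With these numbers
the 10%-threshold P durations span roughly 70–120 ms and the
within-window dispersion sits in the 30–50 ms range, both consistent
with resting adult ECG.  Pd is a population property, not a per-beat
one, so the drunk class widens the jitter half-width by the Pd delta
and rescales the central P width so that the supremum duration shifts
by the Pmax delta.

Study layout defaults: 50 subjects, one session, 2-minute records per
class, mean heart rate 71 bpm.  Between-subject realism comes from a
log-normal common amplitude scale (sdlog 0.15) and a Gaussian heart
rate (SD 3 bpm) shared by a subject's normal and drunk records, so the
class contrast is purely the configured morphology shift.  Within a
record, R-R intervals are Gaussian around the mean interval (SD 40 ms,
truncated at ±3 SD to keep beats ordered).  Noise is additive and
class-independent: 0.05 mV baseline wander at 0.3 Hz, white noise of
SD 0.02 mV, and optional powerline interference (off by default).
Sampling rate is 360 Hz, a common ECG benchmark rate.

What the generator does *not* emulate: autonomic heart-rate variability
structure (respiratory sinus arrhythmia), ectopic beats, electrode
motion artifacts, multi-lead geometry, and any pharmacokinetics of
alcohol.  Passing tests therefore demonstrate that the measurement and
classification chain is faithful under controlled morphology shifts,
not that the classifier would reach the same numbers on real drivers.

## Preprocessing and beat detection

The detection chain is the classic Pan-Tompkins sequence in fixed
order: DC removal and peak normalization, 5–15 Hz band-pass (2nd-order
Butterworth applied forward-backward, so zero phase), five-point
derivative, squaring, and a 150 ms trailing moving-window integration.
Thresholding of the integrated envelope uses running signal/noise peak
estimates with `threshold = noise + 0.25 (signal − noise)` and
exponential updates (gain 1/8), a 200 ms refractory period, and a
search-back at half threshold when a gap exceeds 1.66 times the
running median R-R.  Each trigger is compensated for the trailing
window's group delay and refined to the local maximum of the raw
(DC-removed) signal within ±50 ms, so amplitudes reach the feature
extractor undistorted.  Because thresholds adapt to the normalized
envelope, detection is invariant to amplitude scaling of the input.

Records are trimmed by 30 s before analysis (measurement
stabilization).  Beats are delimited at midpoints between adjacent R
peaks; a beat whose R-R interval to either neighbor deviates more than
40% from the record median is excluded from feature extraction as
corrupted.  A detected beat counts as correctly segregated when it
falls within ±50 ms — about half a QRS duration — of a ground-truth
annotation.

## Wave delineation

Q and S are the minima within 80 ms on either side of R, read off the
raw DC-removed signal.  The low-amplitude P and T waves are located on
a smoothed copy (zero-phase 2nd-order Butterworth low-pass at 18 Hz)
inside [R−250, R−60] ms and [R+100, R+400] ms respectively, with
amplitudes then read from the raw signal at the located index — the
raw sample at a fixed index is unbiased under additive zero-mean
noise, whereas the maximum of a noisy search window is not.  A P peak
must rise at least 5% of the R amplitude above the local baseline to
count.

Two details dominate measurement fidelity and deserve explanation:

**Baseline handling.**  Amplitudes are measured from the local
isoelectric line, not from the record mean — the beats' own area
shifts the record mean by roughly 0.1 mV, which would corrupt the
small P amplitude badly.  Baseline wander is first removed by a
cascaded zero-phase 0.5 Hz high-pass (two passes of a 2nd-order
Butterworth; the cascade is numerically safer than one high-order
filter at so low a normalized cutoff).  The remaining floor level is
estimated per beat from two flat flanks of the P window — the pre-P
(TP) floor at [R−330, R−270] ms and the PR segment at [R−90, R−55] ms
— each summarized by its median, smoothed across neighboring beats
(running median over 9 beats; the floor varies slowly, so pooling
beats is far less noisy than any single beat's 35–60 ms of floor), and
interpolated linearly at the P position so residual linear drift
cancels.

**P-wave duration.**  Onset and offset are the first crossings, moving
outward from the peak, below 10% of the peak amplitude relative to the
local baseline, with linear interpolation between the bracketing
samples and a 15 ms below-threshold persistence requirement that
rejects brief noise dips.  The peak level entering the threshold comes
from a local parabola fit rather than the sample maximum (the maximum
of a noisy signal is upward-biased).  Smoothing broadens the wave, so
every measured duration is corrected by subtracting the smoother's
Gaussian-equivalent broadening in quadrature; that equivalent width is
calibrated once per sampling rate by passing a known Gaussian through
the filter.  The correction is exact for Gaussian waves and
first-order correct for any smooth unimodal wave.

Known limitation: at the default noise level the 10% threshold margin
(≈0.014 mV) is comparable to the smoothed noise floor, so per-beat
durations carry ~10 ms of noise.  Window maxima and ranges (Pmax, Pd)
are order statistics and therefore inflate under this noise in both
classes, which dilutes the recovered between-class percent changes of
Pmax and Pd by a couple of percentage points relative to the injected
values.  The acceptance checks measure exactly this end-to-end
fidelity; the amplitude and interval features are essentially
unbiased.

## Features

A single heartbeat cannot carry a mean, a variance, or a dispersion,
so each feature vector summarizes a sliding window of W = 10
consecutive valid beats (stride 1): means and population variances
(divisor W) of the P, R, S peak amplitudes and of the W−1 R-R
intervals, plus Pmax and Pd over the window's P durations — 10
features in a fixed order.  W = 10 balances moment stability against
responsiveness (≈8 s of ECG at 71 bpm) and is exposed as a
configuration knob.  Features are z-scored with statistics fit on
training rows only; the polynomial and radial-basis kernels are
scale-sensitive and the features span millivolts to milliseconds.
When class counts differ, the majority class is randomly subsampled to
the minority count, since an unequal split biases the SVM margin.

## Weighted composite kernels

Four base kernel families are provided: linear $x \cdot y$, quadratic
$(x \cdot y + 1)^2$, third-order polynomial $(x \cdot y + 1)^3$, and
the Gaussian radial basis $\exp(-\gamma\|x - y\|^2)$ with
$\gamma = 1/(2\sigma^2)$, default $\sigma = 1$ on standardized
features.  The weighted composite kernel applies each family
coordinate-wise and mixes the per-feature kernels:

$$K_c(x, y) = \sum_{p=1}^{10} c_p\, K_p(x_p, y_p), \qquad c_p \ge 0,\
\sum_p c_p = 1.$$

The weights come from the data: $c_p$ is proportional to the magnitude
of the Pearson correlation between feature $p$ and the class labels,
normalized to sum to one, so strongly class-associated features
dominate the kernel.  A conic combination of valid kernels is a valid
kernel, so every weighted Gram matrix is positive semidefinite (this
is property-tested).  Weights are always computed from training rows
only.

## The SVM dual solver

The classifier maximizes the standard dual
$\sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j b_i b_j
K(x_i, x_j)$ subject to $\alpha_i \ge 0$ and
$\sum_i \alpha_i b_i = 0$.  The composite kernels are custom, so the
solver works from a precomputed Gram matrix using sequential minimal
optimization with second-order (maximal-gain) working-set selection;
first-order selection stalls when polynomial kernel values make the
dual ill-conditioned.  The printed dual has no upper bound on
$\alpha$ (hard margin); real cohorts overlap, so a soft-margin box
$0 \le \alpha_i \le C$ with default $C = 1$ is used, with $C = \infty$
available.  Convergence is declared when the maximal KKT violation
falls below $10^{-6}$ or an update cap is reached (the residual gap is
reported; a gap above 0.01 raises an error).  The bias is the average
of $b_s - \sum_i \alpha_i b_i K(x_i, x_s)$ over margin vectors, and
the decision rule is class 1 when $f(x) > 0$ — ties go to "normal",
the conservative choice for an alerting system.  The solver is checked
against an independent interior-point quadratic-programming reference
on small fixtures.

## Evaluation

`cross_validate()` performs stratified 10-fold cross-validation:
balancing, standardization, and kernel weights are fit on each fold's
training rows only, and fold metrics — accuracy
$(T_p+T_n)/(T_p+T_n+F_p+F_n)$, sensitivity $T_p/(T_p+F_n)$,
specificity $T_n/(T_n+F_p)$, with class 1 (drunk) positive — are
averaged unweighted.  By default windows from the same subject stay in
the same fold (group-aware folds), because overlapping windows from
one record are strongly correlated and would otherwise leak across
the train/validation boundary.

The kernel-comparison benchmark (`benchmark_dataset()`) deliberately
uses the other protocol: disjoint windows (stride = W) from a
10-subject cohort under the default study conditions, split by plain
stratified randomization.  With disjoint windows there is no
row-overlap leakage, and pooling a subject's windows across training
and validation mirrors the original protocol in which every volunteer
contributes samples to both sides.  On this benchmark the weighted
kernels match or beat their prime counterparts in a majority of seeds
for every family; the nonlinear families gain several points on
average, while the linear family usually ties at its (near-ceiling)
accuracy — feature weighting mainly helps kernels whose geometry is
sensitive to uninformative coordinates.

## Numerical and degenerate-input choices

* Constant signals normalize to all zeros and are flagged degenerate;
  flat records yield an empty peak list with a warning.
* Constant feature columns get zero weight and map to zero after
  standardization, with a flag.
* If every feature-label correlation vanishes, weights fall back to
  uniform with a warning.
* Ties in the decision function resolve to class 0; ties in local
  maxima resolve to the earliest sample.
* Gram symmetry is exact (`tcrossprod` for the self-kernel case), and
  PSD checks allow an eigenvalue floor of $-10^{-8}$ times the trace.
* All randomness flows from one root seed through named substreams
  (`substream_seed`), so changing one stage never perturbs another;
  identical configurations reproduce artifacts byte-for-byte.

## Problem sizes used in the shipped checks

The package's own test suite exercises the full study layout (50
subjects per class, 2-minute records) for the segregation and
effect-recovery checks, a 10-subject benchmark across 5 seeds for the
kernel comparison, and small algebraic fixtures elsewhere.  These
sizes were chosen so the whole suite completes in minutes on one core
while still using the study-scale cohorts where the claim being
checked is about the cohort.
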