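---
title: "Methods: alpha-band LFP biomarkers for VC/VS DBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha-band LFP biomarkers for VC/VS DBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphadbs)
```

## The problem

Patients with treatment-refractory obsessive-compulsive disorder (OCD) can
receive deep brain stimulation (DBS) of the ventral capsule/ventral striatum
(VC/VS). Modern pulse generators sense local field potentials (LFP) from the
same 4-contact leads that deliver stimulation, but only as bipolar
derivations between contact pairs (6 pairs per lead), in ~20 s snippets at
250 Hz collected during clinic visits. Two clinical questions drive the
analysis implemented here: does alpha-band (7–14 Hz) LFP power index symptom
severity (Y-BOCS, 0–40), and can it predict which contact the clinician
should stimulate — a decision otherwise made by slow trial-and-error
monopolar review?

`alphadbs` implements the full analysis chain as a reusable, tested R
package, together with a synthetic cohort generator with known ground truth
so that every stage can be validated without access to patient data.

## Signal conditioning

Telemetry occasionally drops packets; `reconstruct_sample_grid()` places the
received packets on a uniform grid inferred from packet tick times, linearly
interpolates holes, and records them in a per-sample gap mask. Gapped
samples are retained but masked so that downstream spectral estimation can
skip any analysis window touching a gap — interpolated stretches never enter
a spectrum.

Drifts are removed with a 1 Hz 4th-order Butterworth high-pass applied
forward-backward (`drift_filter()`). Zero-phase application was chosen
because phase distortion inside the narrow alpha band would corrupt the
bipolar-difference topography; the effective magnitude response is the
squared Butterworth response. Line noise is deliberately *not* notch
filtered: a notch deforms the spectrum in a way the spectral model cannot
fit, so 60 Hz is instead absorbed as an ordinary Gaussian peak during
parameterization.

`qc_screen()` is an automated stand-in for manual artifact review. It flags
recordings with more than 0.5% reconstructed samples, any zero-variance 1-s
window (flatline), or a 1-s RMS whose robust z-score exceeds 8. The
threshold of 8 (not a conventional 3–5) is intentional: narrowband alpha
activity is amplitude modulated, so the RMS of clean recordings has heavy
tails and a stricter threshold rejects several percent of clean data. Eight
flags only gross transients. Pairs whose repeats fail *only* the gap flag
are still used, because gapped windows are excluded from the PSD anyway.

Y-BOCS assessments are joined to recordings within a ±7-day window
(`match_clinical()`), preferring same-day visits; equidistant ties go to the
earlier visit for reproducibility.

## Spectral estimation and parameterization

`welch_psd()` uses 1-s Hann windows with 50% overlap; each window's FFT is
zero-padded to 2 s, which is the only way to realize the 0.5 Hz bin spacing
from 1-s windows. Repeated clean snippets of a pair within a session are
PSD-averaged (`average_session_psd()`) so each pair contributes one spectrum
per session. Relative spectra normalize by the 3–100 Hz power sum (percent
units).

The core model (`specparam()`) decomposes log10 power into a Lorentzian
aperiodic component with knee,

$$L(f) = A\,\frac{f_k^{\chi} + f_{min}^{\chi}}{f_k^{\chi} + f^{\chi}},$$

plus up to 8 Gaussian peaks. $A$ is the power at the minimal reliable
frequency $f_{min}$ (1 Hz here), $f_k$ the knee frequency, and $\chi$ the
aperiodic exponent. The parameterization is identifiable whether or not a
knee exists: kneeless spectra converge to $f_k < f_{min}$, and
`classify_knee()` reports a knee only when $f_k > f_{min}$ strictly. A
regularization term $\lambda \sum_n \int_{-\infty}^{0} G_n(f)\,df$ with
$\lambda = 100$ (computed in closed form from the Gaussian CDF) penalizes
peak mass leaking across zero frequency.

Free choices made here, since the underlying optimizer is not fully
specified by the settings alone:

* The objective is least squares on log10 power over 1–65 Hz against linear
  frequency, with bound constraints $\chi \in [-1, 4]$,
  $f_k \in (0.01, 65]$ Hz, $a_n \ge 0$, widths in 1–15 Hz.
* The aperiodic component is first fitted alone with a robust second pass
  that drops the top 40% of residuals (bins sitting on peaks), then peaks
  are seeded iteratively from the largest residual exceeding
  $\max(0.1,\; 2\,\mathrm{sd}(\mathrm{resid}))$, then all parameters are
  refined jointly (analytic gradients). Peaks below the 0.1 minimum height
  after refinement are dropped and the model refit once.
* $R^2$ and per-bin absolute reconstruction error are computed on log10
  power over the fit range.

On noiseless model spectra the fit recovers its generating parameters to
machine-level accuracy; on spectra with realistic noise (log-power sd 0.05,
emulating session-averaged Welch estimates) the test suite requires median
$|\hat\chi - \chi| < 0.1$, alpha center-frequency error < 0.25 Hz and mean
$R^2 \ge 0.95$ over prior-drawn parameters.

The periodic spectrum is the log10 residual after subtracting the aperiodic
fit; alpha metrics (`band_power()`, trapezoidal band average;
`individual_alpha_peak()`; `peak_alpha_power()`, ±2.5 Hz around the
individual peak) operate on absolute, relative, or periodic spectra. Peak
windows overrunning the grid are clipped rather than discarded, so
near-boundary peaks still yield a metric.

## Pseudo-monopolar mapping and contact prediction

Bipolar recordings cannot be attributed to single contacts directly.
`pseudo_monopolar()` estimates per-contact power as the maximum of (1) the
mean power of the three pairs including the contact and (2) the power of
pairs spanning the contact without including it. When an inner contact has
two spanning pairs their maximum is used — consistent with the outer max
rule — with the mean available as an option.

`rank_contacts()` ranks the four estimates (ties broken toward the lower,
more ventral contact index, for determinism), and `selection_curve()`
converts rankings plus clinically chosen ("optimal") contacts into the
cumulative probability of having found the optimal contact within the top k.
The AUC convention is the mean cumulative probability over the first
$n - 1$ tested contacts: the unique simple convention for which the
chance strategy (probability $k/n$ after $k$ contacts) scores exactly 0.5
and a predictor that always ranks the optimal contact first scores exactly
1, for any lead size. Trapezoid-from-origin alternatives violate the
perfect-predictor anchor.

Hemispheres with a double-monopolar configuration (two optimal contacts)
are credited at the better of the two ranks. Significance comes from
permuting rank order within hemispheres (`auc_permutation_test()`); the
null AUC is centered on 0.5 by construction. `rank_difference()` reports
the electrophysiological rank of the optimal contact minus 1, with a
bootstrap CI and left-sided permutation test (chance expectation 1.5 on
four contacts).

For the active-vs-inactive power contrast (`compare_active_inactive()`),
inactive contacts are about three times as numerous, so the statistic
compares the mean normalized active power against means of size-matched
random subsets. The default null draws subsets from *all* contacts — the
standard label-permutation null, which is calibrated under exchangeability.
Drawing only from inactive contacts (available as
`null = "inactive_subsets"`) underestimates the spread of the active mean
(finite-pool subsampling) and is measurably anticonservative; we keep it as
an option for comparability but do not recommend it for inference.

## Spatial mapping

Contact MNI coordinates are pooled across hemispheres by mirroring the
right-hemisphere x coordinate (`pool_hemispheres()`); precomputed nonlinear
flips are accepted as input where available. The spatial peak of alpha
activity is the mean coordinate of the top-5% contacts
(`top_percentile_centroid()`; strict thresholding so a single dominant
contact defines the peak even when the rest tie). Focality is quantified by
the power-weighted moment of inertia

$$I = \frac{\sum_i w_i \lVert \bar r_i - \bar r_{avg}\rVert^2}{\sum_i w_i},$$

with $\sqrt I$ the radius of gyration (mm). Weights must be mass-like, so
periodic (log-residual) power is shifted to a zero minimum before weighting;
the shift is recorded. The permutation null reconstructs weight fields by
permuting hemisphere means across hemispheres and shuffling residuals within
hemispheres (left-sided test for concentration); reconstructed negative
weights are clipped at zero with a logged count.

2D heatmaps project contacts onto an anatomical plane and interpolate power
on a regular grid. No installed package provides Delaunay-based linear
scattered interpolation, so the package uses inverse-distance weighting —
exact at the data points, constant-preserving, masked outside the convex
hull — followed by Gaussian smoothing with $\sigma = \mathrm{FWHM}/2.355$.
The FWHM (default 0.75) is interpreted in grid cells, configurable; these
maps are visualization artifacts and only their invariants (uniform input →
uniform output; mean preservation; hotspot localization) are guaranteed.
Structure border distances (`border_distance()`) use surface point clouds or
the boundary voxels of a mask through its affine.

## Cohort statistics

Severity groups are a median split on S1 Y-BOCS (ties to "more severe"; an
explicit threshold such as 30 can be supplied). Frequency-wise group
contrasts and Y-BOCS correlations use cluster-based permutation correction:
per-bin t (Welch or paired) or rank-correlation t statistics are thresholded
two-sided at a cluster-forming $\alpha$ of 0.05 (the family-wise $\alpha$ is
0.01; the forming threshold is a free parameter of the method and is
configurable), contiguous same-sign bins form clusters scored by summed t,
and the null is the maximum absolute cluster mass over label permutations or
within-unit sign flips. The family-wise error of this construction is
verified by simulation in the test suite.

Longitudinal co-fluctuation uses within-lead changes relative to the first
session: Y-BOCS as percent improvement and alpha as a log-ratio, correlated
by Spearman's rank. Because periodic alpha can be nonpositive, log-ratios on
periodic power apply a per-cohort affine shift to positivity, recorded in
the output. Mixed-effects models (`fit_lme()`) — Y-BOCS on alpha, hemisphere,
their interaction, stimulation amplitude, and days since DBS onset with a
random patient intercept — are deliberately delegated to `lme4`/`lmerTest`
(REML, Satterthwaite F tests): this stage is standard statistical machinery,
not the package's contribution. Alpha and amplitude are centered;
hemisphere L is the reference level. A caveat surfaced by testing: REML
point estimates are not exactly invariant to duplicating every row (variance
components re-balance), so the replication-invariance property holds only
approximately.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 13 patients, two 4-contact
leads each (2 mm contact spacing, jittered mostly-dorsoventral trajectories),
4 sessions ~90 days apart (consistent with several hundred recordings over
roughly a dozen patients), 20 s bipolar snippets at 250 Hz for all 6 pairs.
Spectra follow the Lorentzian-knee model with priors $A \in [2, 20]$
µV²/Hz, $\chi \in [1, 2]$, a 7% probability of a true knee
($f_k \in [2, 10]$ Hz, otherwise sub-$f_{min}$), per-hemisphere alpha peaks
at 8–12 Hz and beta peaks at 15–30 Hz, plus a 60 Hz line component. LFPs
are realized as spectrally shaped Gaussian noise whose expected PSD equals
the model — any process with the stated PSD suffices for what the pipeline
measures.

The planted structure the pipeline must recover:

* a spatial alpha hotspot at MNI (−10.12, 4.07, −4) with Gaussian decay
  (length 4 mm) of contact alpha amplitude;
* a severity factor per patient that multiplies alpha amplitude and drives
  S1 Y-BOCS affinely (16–38 over the severity range, score noise sd 1.5);
* longitudinal improvement trajectories mirrored in the alpha severity
  factor (so improvement co-occurs with alpha suppression);
* active-contact labels equal to the true-alpha argmax, flipped with
  probability 0.15 by default to emulate imperfect clinical selection;
* 0.2% per-packet loss, reconstructed and gap-masked as in real telemetry.

What the generator does *not* emulate: cardiac and movement artifacts,
electrode impedance drift, circadian or medication effects, non-Gaussian
burst dynamics of alpha, and true anatomical structure geometry
(border-distance tests use labeled synthetic spheres). Passing tests therefore demonstrate
the pipeline's correctness and sensitivity under the stated generative
model, not robustness to every pathology of real recordings.

## Problem sizes and numerical choices

The test suite validates statistical calibration with 200 replicates at
1,000 permutations per test, parameter recovery on 100 prior-drawn spectra,
and end-to-end cohort recovery over 10 seeds at the default 13-patient
scale; production analyses default to 10,000 permutations/resamples.
Permutation p-values use the +1 correction, so p > 0 always. All stochastic
stages take explicit seeds, and reports are pure functions of
(inputs, config). Degenerate inputs are conventions, not errors, where a
cohort run must not abort: min-max normalization of an all-equal lead maps
to zeros with a flag; identical weights give a focality p of 1; zero-variance
frequency bins never form clusters.
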