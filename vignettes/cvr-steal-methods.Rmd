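---
title: "Methods: CVR mapping, steal detection and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CVR mapping, steal detection and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrsteal)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the order the pipeline applies them. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The stimulus and the signal model

The vasodilatory stimulus is a boxcar end-tidal CO₂ protocol: a baseline
epoch at the subject's resting PetCO₂, a hypercapnic step, and a recovery
epoch (defaults 100 s / 80 s at +10 mmHg / 120 s, sampled at the 2 s
repetition time). Frames are assigned to epochs by half-open intervals on
acquisition time, so a frame landing exactly on a transition belongs to
the later epoch.

The synthetic generator models each voxel as a pure scaled copy of the
(optionally delayed) stimulus plus white Gaussian noise:

$$S(v, t) = B \left(1 + \frac{\mathrm{CVR}(v)}{100}\,
  \big(\mathrm{PetCO_2}(t - \delta) - \mathrm{PetCO_2^{rest}}\big)\right)
  + \varepsilon(v, t), \qquad \varepsilon \sim N(0, \sigma^2).$$

No drift, hemodynamic response convolution, or physiological noise
spectrum is included by default: the point of this model is that the CVR
definition below inverts it *exactly*, so estimator correctness can be
tested to machine precision. Realistic confounds (drift, delay) are
available as explicit parameters for robustness checks, not as defaults.

## CVR estimation

CVR is the percentage BOLD signal change per mmHg of CO₂. The estimator
regresses each voxel's time series on the delayed, baseline-centered
PetCO₂ trace by ordinary least squares with an intercept and scales the
slope by the voxel's baseline-epoch mean:

$$\mathrm{CVR}(v) = \frac{100\,\hat b(v)}{\bar S_0(v)}
  \quad [\%\Delta\mathrm{BOLD}/\mathrm{mmHg}].$$

The regression form was chosen over direct epoch differencing because it
uses every frame, tolerates ramp frames and drift regressors, and reduces
algebraically to the epoch-ratio form
$(\bar S_\mathrm{plateau} - \bar S_0)/(\Delta \mathrm{PetCO_2}\,\bar S_0)$
on an ideal noiseless step — an equivalence the test suite asserts to
1e−9. Two properties follow from the ratio form and are tested: rescaling
the whole series leaves CVR unchanged, and doubling the step amplitude at
fixed CVR leaves the estimate unchanged.

The hemodynamic delay is a single global scalar (default 0 s for
synthetic data), applied as a nearest-frame shift of the regressor.
Per-voxel lag optimization, spatial smoothing, detrending and motion
regression are deliberately out of scope; the delay and all thresholds
are configurable so a caller with preprocessed clinical data can match
their upstream pipeline.

Voxels with non-positive baseline signal (air, background) are flagged
undefined (`NA`) rather than zero-filled, and every downstream mean skips
them. A constant stimulus is a hard error, not a zero map.

## Quality gates

Two exclusion rules are applied per subject, with strict inequalities:

* **Motion** — mean framewise displacement over the $n-1$ adjacent-volume
  pairs must not exceed 2 mm. FD is the Power-style sum of absolute
  backward differences, rotations converted to arc length on a 50 mm
  sphere. The metric's rotation radius is not standardized across the
  field, so it is a parameter; 50 mm is the dominant convention for an
  adult head.
* **Stimulus adequacy** — the realized CO₂ step, measured as the plateau
  median minus the baseline median, must be at least 6 mmHg. Medians are
  used for robustness to transient end-tidal sampling spikes, and the
  first 10 s after each transition are trimmed so ramp frames do not
  dilute the plateau.

A subject at exactly the threshold passes (mean FD = 2.0 mm, step =
6.0 mmHg), because the exclusion rules are "greater than" and
"less than" as stated.

## Steal classification

A voxel exhibits steal when its reactivity is paradoxically negative
*and* atlas-atypical:

$$\mathrm{CVR}(v) < 0 \quad \text{and} \quad
  Z(v) = \frac{\mathrm{CVR}(v) - \mu_\mathrm{atlas}(v)}
              {\sigma_\mathrm{atlas}(v)} \le -z_0, \qquad z_0 = 2.$$

The atlas criterion is stated in the field as "exclude voxels with
Z-score < 2". Read literally against a healthy atlas with positive mean
CVR, every negative voxel has Z far below +2 and would be excluded,
emptying the mask; the stated intent — keep only negative voxels that
differ *significantly* from the healthy cohort — requires the deviation
to be at least 2 SD *below* the atlas. The package therefore implements
$Z \le -z_0$, with $z_0$ configurable. Whether the reference dispersion
is the atlas between-subject SD or pooled voxel noise is likewise not
standardized; the package takes voxelwise mean and SD maps as explicit
inputs so either convention can be supplied.

Two structural properties are enforced by tests: the mask is monotone
non-increasing in $z_0$, and thresholding decomposes as the permissive
mask intersected with $\{Z \le -z_0\}$. An optional 26-connectivity
cluster-size filter exists but defaults to off, preserving the voxel-level
definition.

## Overlap volumetrics

Volumes are voxel counts times the voxel volume (mL); no partial-volume
weighting. The steal mask is partitioned against the lesion mask into
within-lesion and extra-lesional compartments, which sum to the total
exactly in voxel counts. Coverage percentages with a zero denominator are
flagged undefined rather than forced to 0 — subjects with no steal inside
the lesion legitimately report 0%, but an empty steal mask has no defined
"percent inside". Per-subject territory statistics clip the steal mask to
the affected-side ACA+MCA labels, treating the reported "steal in ACA+MCA
territory" as a stroke-side quantity; the clip is configurable.

## Cohort statistics

* **Quantiles.** All medians and IQRs use linear interpolation at
  position $(n-1)q$ (type 7). This is the convention under which the
  packaged reference table reproduces its published lesion-volume median
  and IQR exactly; one published steal IQR ("8–64") is not reproducible
  from the printed two-decimal values under any common convention and is
  reported, not asserted.
* **Rank correlation.** Spearman is Pearson on midranks, p-values from
  the t approximation on $n-2$ df. The partial variant rank-transforms
  every variable, residualizes the ranked responses on the ranked
  covariates by least squares with intercept, and correlates the
  residuals ($n-k-2$ df) — the standard "partial Spearman", since the
  estimator behind published partial rank correlations is rarely stated.
  With no covariates it *is* the plain estimator, by construction.
* **Proportional odds.** The cumulative-logit model
  $P(Y \le j\,|\,x) = \mathrm{logit}^{-1}(\alpha_j - x^\top\beta)$ is fit
  by damped Newton ascent: analytic score, Hessian by central differences
  of the score, step halving until the log-likelihood is non-decreasing
  and the cutpoints stay ordered, convergence at score max-norm below
  1e−8 (iteration cap 100, flagged if hit). Standard errors come from the
  inverse observed information; CIs are Wald. Discharge NIHSS enters as
  ordered categories exactly as observed, without binning. Separation in
  small cohorts shows up as exploding standard errors and is surfaced,
  not hidden.
* **Brant–Wald.** The proportional-odds assumption is checked by fitting
  the $J-1$ cumulative binary logits, stacking their slopes, and forming
  the Wald statistic for slope equality with the between-split covariance
  $w_{jl} = \pi_l - \pi_j \pi_l$; the omnibus statistic is
  $\chi^2_{(J-2)k}$. Calibration (type-I error near 0.05, high power
  under a strong slope violation) is verified by simulation in the test
  suite.
* No multiple-testing correction is applied anywhere, and p-values are
  reported at full precision.

## The synthetic cohort: what it emulates, what it does not

The cohort generator reproduces the *statistical* structure the analysis
assumes, not brain anatomy:

* Lesion volumes are log-normal with `meanlog = log(26.3)`,
  `sdlog = 0.955`, matching the reference cohort's median and IQR
  (26.30, 14.58–52.84 mL).
* Extra-lesional steal volume is coupled to lesion volume by a Gaussian
  copula whose Pearson parameter $2\sin(\pi\rho_s/6)$ yields the target
  Spearman correlation (default 0.77) exactly in population — an exact,
  testable construction. Its marginal is log-normal with the reference
  median (13.5 mL) and `sdlog = 1.3`: the value matching the printed IQR
  exactly (≈1.76) implies a tail with steal volumes beyond any
  hemispheric volume, so the scale is moderated toward that physical
  ceiling while keeping the median.
* The fraction of the lesion covered by steal is Beta(0.6, 1.8), placing
  its median near the ~20% seen in the reference cohort.
* Age is truncated normal (69 ± 15, 18–100 y); admission NIHSS is a
  rounded log-normal with median 10; groin-puncture-to-MR time is
  log-normal with median 30 h.
* Discharge NIHSS is drawn from the proportional-odds model with per-unit
  effects 0.04/mL (extra-lesional steal), 0.02/mL (lesion), −0.06/year,
  0.17/NIHSS point, the published adjusted point estimates. Cutpoints
  are derived from a geometric-decay base distribution over categories
  0–18 (median 2 at the reference covariate profile), anchored at the
  covariate-law medians so that zero slopes reproduce the base rates
  exactly.
* A configurable fraction (default 5/26) of subjects carries an injected
  quality failure — scaled motion giving mean FD 2.5 mm, or a 4 mmHg
  step — alternating between the two modes.

In imaging mode each subject additionally gets a phantom whose geometry
realizes the drawn volumes: an ellipsoidal lesion (1:2:1 aspect) in the
affected MCA territory, a concentric steal core covering the drawn lesion
fraction, and extra-lesional steal as a concentric shell. On the default
desk-scale grid (32×32×16 voxels at 3 mm, seconds per subject) the
containment clamp saturates lesions near ~40 mL and lesion-plus-steal
near ~78 mL; realized volumes are re-measured from the masks, so
downstream stages remain internally exact, and the cohort-level
stochastic tests use the tabular generator, which has no such ceiling.

Passing tests on these phantoms therefore demonstrates estimator and
pipeline correctness under the stated signal model — they do not
demonstrate robustness to realistic fMRI confounds (susceptibility
artifacts, physiological noise, registration error), which are explicit
non-goals.

Determinism: a cohort is a pure function of its seed; per-subject
substream seeds are drawn once from the cohort seed, and identical runs
reproduce outputs byte-for-byte.

## Problem sizes used in validation

The test suite and acceptance script validate at sizes chosen to make
Monte-Carlo error small relative to each tolerance: coefficient recovery
with 200 replicates of n = 2000; Brant size with 500 replicates of
n = 500 and power with 200; rank-coupling at n = 2000; QC-fraction
recovery at n = 200; steal recovery on 10 seeded default-noise phantoms;
noiseless inversion on full 32×32×16 phantoms.

## Known limitations

* Inputs are assumed co-registered on one voxel grid; no world-space
  registration is performed (nearest-neighbour resampling of masks is the
  only concession, behind an explicit policy flag).
* The published regression coefficients for discharge NIHSS and the
  0.77/0.76 correlations cannot be verified from the packaged table —
  the per-subject covariates behind them are not published, and printed
  two-decimal rounding already shifts rank statistics (the plain Spearman
  of the printed columns is ≈0.71). The regression and correlation stages
  are validated by simulation instead, and the pipeline reports both
  plain and adjusted estimates without asserting either reference value.
* GM/WM statistics require a caller-supplied tissue-label volume; no
  segmentation is performed.
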