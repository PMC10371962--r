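---
title: "Dual-time-point PET radiomics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-time-point PET radiomics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
kinetic model, the feature conventions, the harmonization and modeling
protocols, what the synthetic-data generators do and do not emulate, and the
choices made where the underlying methods leave room.

```{r setup, message = FALSE}
library(dtpradiomics)
```

## The two-point Patlak model

For an irreversibly trapped tracer such as FDG, the Patlak transformation
makes tissue uptake linear in "stretched time": C(t)/Cp(t) plotted against
∫Cp/Cp(t) has slope Ki (the net influx rate, 1/min) and intercept V (the
reversible distribution volume). Two static acquisitions give two points on
that line, and `compute_ki_map()` evaluates the slope voxel by voxel:

$$K_i \;=\; \frac{C(t_2)/C_p(t_2) - C(t_1)/C_p(t_1)}
{\int_0^{t_2}\! C_p\,d\tau / C_p(t_2) - \int_0^{t_1}\! C_p\,d\tau / C_p(t_1)}.$$

Assumptions worth keeping in view:

* **Irreversibility.** No k4 washout between the two time points; with late
  acquisition times (defaults 61 and 133 min, typical clinical values) this
  is the standard regime for FDG in tumours.
* **A shared plasma curve shape.** Full arterial sampling is replaced by a
  population curve scaled to the patient. `input_function()` is a linear
  rise to a peak (default 1 min) followed by a tri-exponential decay; the
  published population curves do not print their coefficients, so the
  defaults here are the package's own plausible FDG-like shape and every
  parameter is an argument. Because the Patlak ratio is homogeneous of
  degree zero in Cp, the *shape* matters only through the normalized
  integral terms, and any smooth decreasing curve exercises the estimator
  identically — this is property-tested, not assumed.
* **Scaling anchor.** `blood_pool_activity()` averages two spherical VOIs
  (15 mm left-ventricle, 10 mm left-atrium, equal weight) on the static
  image; `scale_input_function()` applies the single multiplicative factor
  that makes the curve pass through that value at t1.
* **Co-registration.** The delayed volume must arrive on the t1 grid; a
  grid-equality check makes misalignment a hard error rather than a silent
  resample. Registration itself is deliberately out of scope.

The closed-form integral of the exponential family is what allows *exact*
tests: on noiseless data generated by the same model, recovery of a planted
Ki field is an algebraic identity, and the test suite asserts it to below
1e-6 /min across random tri-exponential curves. A pathological configuration
(non-positive denominator, zero plasma value) is an error, never a NaN map.
Negative slopes are preserved in the map; they only clamp at feature time
through the absolute discretization bounds.

## Feature conventions

The 65-feature panel is computed after two fixed preprocessing steps:
resampling to 4 mm isotropic voxels (trilinear for intensities, nearest
neighbour for masks) and absolute-bound discretization into 64 gray levels
over [0, 20] on the SUV scale (bin width 0.3125). Ki maps are multiplied by
100 first so both image types share the same intensity scale. The bounds are
absolute by design: adding a constant to an image *changes* its features,
and a test asserts exactly that.

Convention decisions, each of which changes feature values and is therefore
fixed and tested against brute-force enumeration oracles:

* **Direction handling.** GLCM and GLRLM accumulate the 13 unique 3D
  directions at voxel distance 1 into a single merged matrix before feature
  computation; GLZLM zones and the NGLDM neighbourhood use 26-connectivity.
* **Degenerate lesions.** A single-gray-level lesion has an undefined GLCM
  correlation (set to 1), zero entropy/contrast, NGLDM coarseness at a 1e6
  cap, and skewness/kurtosis/excess kurtosis all set to 0 when the SD is 0
  (so the excess-kurtosis = kurtosis − 3 identity holds only for SD > 0).
  Deterministic fills keep every vector finite.
* **Surface and compacity.** The surface is exposed voxel faces × face
  area. That overestimates smooth surfaces: the digitized-ball limit is
  exactly 2/3 of the analytic sphericity (each axis contributes twice its
  projected area), so sphericity values sit well below 1 for real lesions —
  a documented bias of the face-count convention, not an error. Compacity is
  V/(√π S^{3/2}) with V in mm³ and S in mm².
* **Peak.** Mean over a 0.5 mL sphere centred on the maximum voxel,
  intersected with the VOI.
* **Quantiles and moments.** Linear-interpolation quantiles; sample SD;
  population-moment skewness/kurtosis.
* **AUC-CSH.** The cumulative intensity–volume histogram is a step
  function; its integral over the [0, 1] fraction axis is computed exactly
  (it equals the mean of the clamped intensity fractions) rather than on a
  grid.
* **Entropy bases.** "Entropy" is natural log, "Entropy_log2" base 2, in
  both the GLCM and histogram families.

Segmentation takes the maximum *within the caller's seed region*, not the
whole volume, so multiple lesions per study segment independently; the 30%
threshold mask is restricted to the 26-connected component containing the
maximum voxel.

## ComBat harmonization

`combat_fit()` implements the parametric empirical-Bayes location/scale
model: features are standardized by their grand mean and pooled variance,
per-batch means and variances of the standardized data are shrunk with a
normal / inverse-gamma prior pair (hyperparameters by method of moments) via
the usual iterative joint update (relative tolerance 1e-6), and
`combat_apply()` performs the adjustment. Two properties of this estimator
matter for interpretation:

* The residual per-feature gap between centers after adjustment is
  shrinkage plus sampling noise, O(1/√n) — so recovery of planted effects is
  judged on cohort-average gaps and SD ratios, and "idempotence" and
  grand-mean preservation hold to shrinkage noise, not machine precision.
* Because the adjustment equalizes *in-sample* batch means, a post-hoc
  between-center t-test is conservative (rejects far below nominal); the
  5% calibration lives in the outcome-class comparison, which harmonization
  leaves untouched.

The fit/apply split exists because fitting on all lesions before a
train/test split leaks test information into the transform. The default in
the modeling protocol is fit-on-training; `combat_fit_on = "all"` reproduces
the common (leaky) practice for comparison. An optional outcome covariate
can be protected during fitting. The implementation is cross-checked against
`sva::ComBat` to 1e-4 on shared fits.

## Univariate and multivariate protocols

The univariate screen computes, per feature and per arm (static/DTP ×
before/after harmonization), the direction-free AUC against outcome with its
DeLong variance, a two-sided p against AUC = 0.5, and BH q-values adjusted
within arm; paired DeLong tests then compare arms feature by feature, and
the improved / decreased / no-difference tally partitions the panel at
q < 0.05. Spearman tiers use |ρ| with boundaries at 0.5 and 0.7 (closed on
the upper side: ρ ≥ 0.7 is "high"), the conventional reading of overlapping
printed inequalities.

The modeling protocol per repetition: an 80/20 split grouped by patient
(same-patient lesions never straddle the split; a lesion-level mode exists
behind `split_by` for comparison), harmonization fitted on training lesions,
greedy MID mRMR to 10 features (the combined variant selects 10 per feature
set, pools the 20, and re-selects 10), an inner 80/20 validation split, and
a random hyperparameter search over gradient-boosted trees in which each
candidate is scored by its mean validation AUC over bootstrap resamples of
the inner-training lesions. The "bootstrapped model with 1000 repetitions"
phrasing of such protocols is ambiguous between resampling the data and
repeating the search; this package reads it as bootstrap resampling within
the search, with both counts configurable (`n_boot`, `n_candidates`). The
winner is refit on the full training split and measured once on the
untouched test split; ACC/SEN/SPE use a 0.5 probability cut ("responding"
positive), AUC is threshold-free; the 95% CI over repeats is percentile.
Mann–Whitney tests compare variants on the per-repeat metric vectors.

mRMR mutual information uses three-state discretization at μ ± σ with the
*population* SD and inclusive boundaries — with a strict sample-SD rule a
balanced two-valued feature collapses into the middle state and carries no
information, which would silently disable the selector on indicator-like
features. The outcome is used as is.

## What the generators emulate — and what they do not

`simulate_dtp_study()` builds tissue curves directly from the Patlak model:
background with a small Ki and an intercept chosen to hit the stated
background SUV at t1, spherical lesions whose Ki field is mean × (1 +
amplitude × Gaussian random field) clipped at zero (seeded FFT-based field,
stated correlation length, unit variance), a blood-pool sphere carrying pure
Cp(t), and independent multiplicative Gaussian noise per time point. This
gives exact ground truth for Ki and controllable heterogeneity. It does
*not* emulate scanner physics: no point-spread function, reconstruction
artifacts, attenuation/scatter, Poisson counting statistics, or motion. A
green Patlak-recovery test therefore certifies the estimator's algebra and
the pipeline's bookkeeping, not robustness to reconstruction effects.

`simulate_cohort()` generates two-center lesion tables with Gaussian
within-class features, an exact planted class shift (in pooled-SD units) on
named features, and per-center location/scale batch transforms; patients
carry 1–3 lesions and outcome prevalence defaults to 75/126, the responding
fraction of a two-center lymphoma cohort of 126 lesions in 45 patients.
`simulate_image_cohort()` instead pushes every lesion through the full image
chain (phantom → blood pool → Ki map → segmentation → transfer → 65 + 65
features) and then plants the outcome and batch effects in feature space on
top of the image-derived features. Planting in feature space is a deliberate
design: it keeps the effect size exact (image-level knobs such as lesion Ki
or texture amplitude have no fixed conversion into pooled-SD units) while
every image stage still runs and contributes realistic feature
distributions and correlations.

## Calibration at cohort scale

One subtlety drove the design of the end-to-end checks: a *fixed* finite
cohort carries a chance association between outcome labels and features that
is the same in every protocol repetition. Across independent zero-effect
image cohorts of ~40 lesions the per-cohort mean test AUC ranged from about
0.34 to 0.70 — entirely without signal. A confidence interval computed over
repeated splits of one such cohort therefore cannot be expected to bracket
0.5, for any correct implementation. The calibration check consequently
draws a fresh null cohort per replicate (20 table-level cohorts of ~120
lesions, the scale of the motivating study, with planted batch effects,
through the harmonize → select → train/evaluate chain) and takes the CI over
those cohort-level replicates; the power and monotonicity checks use the
image-chain cohort with planted 0.5/1/2-SD effects. At these problem sizes
(24³ phantoms at 4 mm, ~45-lesion image cohorts, 20 repeats, 8 candidates ×
25 bootstraps) the whole acceptance computation runs in a couple of minutes
on one core; the same quantities scale up by raising `n_repeats`, `n_boot`
and the cohort sizes in configuration.

## Known limitations

* Two-point Patlak ignores k4 washout and inherits any bias of the
  population input-function shape; only the scale is patient-specific.
* Feature values follow this package's fixed conventions; other radiomics
  programs differ in aggregation, surface estimation and histogram details,
  so cross-software numeric parity is not a goal (the oracles are).
* The non-parametric ComBat variant and reference-batch mode are not
  implemented.
* The phantom does not simulate scanner physics (see above), and lesions
  are spherical; shape features on synthetic cohorts therefore vary mainly
  through radius.
* With ~45 patients' worth of lesions, test splits are small and per-repeat
  metrics are noisy; conclusions should rest on the repeat summaries, and
  on the fresh-cohort calibration logic described above.
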