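---
title: "Methods: cognition-eye-brain association analysis on synthetic multimodal cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cognition-eye-brain association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cebconn)
```

## The analysis this package implements

In studies of the Alzheimer's disease spectrum (ADS: healthy controls,
subjective cognitive decline, mild cognitive impairment, AD dementia),
three families of measurements are available per subject: cognitive test
scores (MMSE, MoCA, BNT, CDT, BDST, TMT-A/B), resting-state fMRI metrics
of spontaneous brain activity, and retinal biometrics from OCT
angiography. The question is whether these co-vary: does reduced
spontaneous activity in a brain region track both a cognitive deficit and
a retinal change?

The package implements the full chain as reusable functions:

1. **fMRI metrics** (`process_fmri_subject()`): discard the first 10
   volumes of the run, remove the per-voxel linear trend, regress out
   nuisance signals (the Friston-24 motion expansion plus the mean global
   signal, and white-matter/CSF means when supplied), then compute
   voxel-wise **FALFF** — the fraction of square-root spectral power in
   the 0.01-0.1 Hz band — and **ReHo** — Kendall's coefficient of
   concordance (W) between each voxel and its 26 neighbors, computed on
   band-pass-filtered residuals. Both maps are divided by their in-mask
   mean ("standardized"); Gaussian smoothing (FWHM in mm) is available.
2. **Retinal morphometry** (`retinal_biometrics()`): from binary
   segmentation masks, the foveal avascular zone (FAZ) area (largest
   8-connected component, pixel count times pixel area) and perimeter
   (traced boundary polygon), retinal blood vessel curvature (RBVC, mean
   curvature along skeleton centerlines), and mean RNFL / GCL-IPL layer
   thickness.
3. **Group statistics** (`cohort_stats_table()`): chi-square tests on
   categorical demographics, one-way ANOVA for age (including the
   summary-statistics form that reproduces a published table from its
   printed means and SDs), Kruskal-Wallis for scores.
4. **Two-stage association** (`stage1_voxelwise()`, `stage1_roiwise()`,
   `stage2()`): the multivariable model
   `Y = b0 + b1 x_obj + b2 age + b3 sex + b4 edu + b5 hyp + b6 dia
   [+ b7 ETIV]`,
   fitted per voxel (or per DKT region) with the cognitive score as `Y`
   in stage 1 and the ophthalmic biometric as `Y` in stage 2, stage 2
   being confined to the stage-1 significant set.
5. **Synthetic cohort** (`generate_cohort()` and friends): everything
   above is exercised end-to-end on simulated data with planted,
   recoverable effects.

## Family-wise error control

Voxel-wise inference uses the permutation distribution of the maximum
|t|: under Freedman-Lane residual permutation, the response is reduced to
its covariate-model residuals, the residuals are permuted over subjects,
and the per-voxel t statistic for the predictor of interest is recomputed
(via Frisch-Waugh residualization, which makes the scan a single
matrix-vector product per permutation). A voxel survives when
`(1 + #{permutation max-|t| >= |t|}) / (n_perm + 1) <= alpha`. This
choice is assumption-light and exactly calibrated at desk scale, which
the package verifies by simulation (family-wise error 0.025 over 200 null
cohorts at nominal 0.05 in the shipped acceptance run); random-field
theory is deliberately out of scope. Region-wise inference uses strict
Bonferroni, `p < 1/62` over the 62-region DKT registry, and stage 2
corrects over the reduced domain only (permutation FWE over the selected
voxels; Bonferroni `1/|domain|` over selected regions). Stage-2 masks are
asserted to nest inside stage-1 masks on every run.

We model cognition as the stage-1 response (score ~ metric), matching the
single published model equation; inference on `b1` is symmetric in the
bivariate pair given the covariates, so this choice mostly affects
interpretation, not selection.

## Numerical conventions that matter

- **FALFF**: ratio of summed DFT amplitudes (square-root power), DC bin
  excluded, band inclusive on both edges (`f_lo <= f <= f_hi` on the DFT
  grid). The amplitude (not power) convention follows standard toolbox
  practice; the two phrasings in circulation disagree and this one is
  pinned by tests (an on-bin in-band sinusoid gives exactly 1).
- **Band-pass before ReHo only**: the band enters FALFF through the
  spectral ratio itself, so no filtering is applied first; ReHo is
  computed on 4th-order zero-phase Butterworth-filtered residuals
  (forward-backward application with odd-reflection padding, vectorized
  across voxels; `signal::filtfilt` is the cross-check in the tests).
- **KCC ties**: `W = 12 S / (k^2 (n^3 - n) - k sum T_j)` with the usual
  tie term; all-tied neighborhoods give 0 with a warning, never NaN.
  ReHo neighborhoods use in-mask neighbors only; fewer than 2 members
  gives 0.
- **Friston-24 layout**: `[R, R^2, R_lag1, R_lag1^2]`, first lagged row
  zero.
- **Perimeter**: traced 8-connected boundary polygon with segment lengths
  1 and sqrt(2). This estimator is simple and testable (a 10 x 10 px
  square gives exactly 0.36 mm at 0.01 mm pixels) but carries the known
  ~5% staircase overestimate for circles; it is the same for all subjects
  and so cancels in associations.
- **Curvature**: `kappa = |x'y'' - y'x''| / (x'^2 + y'^2)^(3/2)` from
  first/second index-wise gradients (central differences, one-sided at
  open ends). On integer-pixel centerlines the staircase dominates raw
  second differences, so `rbvc()` smooths the coordinate functions with a
  Gaussian of sigma = 3 px before differencing, pools only points with
  full kernel support, and drops points whose smoothed arc speed falls
  below 0.5 px/step (over-smoothed stubs). With sigma = 3 the estimator
  recovers 1/R within ~2% for circles of radius 25-60 px; curvature at
  radii well above ~80 px is under-resolved at this smoothing scale.
  `path_curvature()` itself defaults to no smoothing so exact-coordinate
  inputs behave analytically.
- **Connectivity**: 8-connectivity everywhere (components, boundaries,
  skeletons). Skeletons come from Zhang-Suen thinning (implemented here;
  no installed R package provides it); branches are split at junction
  pixels identified by crossing number (>= 3 distinct branches), and the
  junction's immediate neighborhood is removed with it since branch tips
  around a junction are mutually diagonal.
- **Coordinates**: voxel/pixel indices are 1-based inside R; world (mm)
  coordinates apply the NIfTI affine to 0-based indices, matching the
  on-disk convention. Peak ties break to the smallest linear index.

## The synthetic cohort: what it emulates and what it does not

`cohort_config()` defaults encode the study conditions: group sizes
16/35/18/7 (HC/SCD/MCI/AD), the published per-group sex, hypertension
and diabetes rates and age means/SDs, cognitive score centers at the
published group medians with clinically plausible spreads, TR 2 s with
185 volumes (10 discarded), and a 62-region DKT thickness table. One
latent "neural integrity" value per subject (group shift + standard
normal; shifts 0 / -0.3 / -1 / -2 across HC/SCD/MCI/AD) drives three
channels:

- an fMRI blob (radius 2 voxels at the grid center) whose in-band
  (0.05 Hz) sinusoid amplitude is `max(0, 2 + 0.8 x latent)` in units of
  the baseline noise SD, with an **independent random phase per voxel** —
  phase-coherent signal would leak into the mean global signal and be
  removed by nuisance regression, and coherence is the separate
  `reho-coherence` channel's job;
- the BDST score, slope 1.5 points per latent SD (score SD 1.2);
- the FAZ area, slope -0.05 mm^2 per latent SD (noise SD 0.015), realized
  by drawing the FAZ ellipse at the implied radius.

These couplings were sized once, at design time, so that the stage-1
standardized association is about 1 SD at n = 76 — the regime in which
the two-stage procedure should detect the planted effect in at least 80%
of cohorts; the shipped acceptance run measures 100/100 detections with
the planted (negative) sign at every detected peak. Score generation is
continuous Gaussian (no integer truncation) to keep the regression
assumptions transparent; sex/hypertension/diabetes are 0/1; motion is a
small-step random walk far below a 3 mm / 3 degree exclusion bound;
volumes are generated on a common grid, i.e. post-realignment and
post-normalization, since those steps are out of scope. One eye per
subject is modeled.

What the generator does **not** emulate: hemodynamic response shapes,
scanner drift and physiological noise spectra, anatomical variability of
the gray-matter envelope, realistic vessel trees (vessels are radial
curves with sinusoidal tortuosity), or fundus photometry. Passing tests
therefore demonstrate that the estimators and the two-stage inference are
correct and calibrated on data satisfying their assumptions — not that
the pipeline is robust to the artifacts of real acquisitions. A side
effect of the amplitude channel worth knowing: strong independent-phase
sinusoids slightly *lower* blob ReHo relative to background, so the two
functional channels are not fully orthogonal.

## Problem sizes used in the shipped simulations

Full-scale defaults (20 x 20 x 12 voxels, 185 volumes, 160 px retina)
run in a few seconds per subject. The simulation studies use reduced
configurations chosen as the smallest grids on which the claims are
meaningful: null calibration on 10 x 10 x 6 grids with 60 volumes
(200 replicate cohorts, n = 76, 300 permutations); planted-effect
recovery on 12 x 12 x 8 grids with 100 volumes and 96 px retinas
(100 replicate cohorts, measured — not planted — FAZ areas). The
`desk_cohort_config()` helper pins these configurations.

## Known limitations

- The permutation engine permutes subjects i.i.d.; exchangeability
  violations (site, family structure) are not modeled.
- Listwise deletion is the only missing-data policy.
- RBVC's absolute scale depends on the smoothing sigma; comparisons are
  meaningful within a fixed configuration.
- The DKT registry is the label set only; no atlas geometry ships with
  the package (region-wise analyses consume thickness tables).
- Group labels are not covariates in the pooled two-group models, so a
  stage-1 hit means "score and metric co-vary in the pooled sample",
  which includes between-group separation by design.
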