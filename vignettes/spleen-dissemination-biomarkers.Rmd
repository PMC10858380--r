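---
title: "Spleen-referenced dissemination biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spleen-referenced dissemination biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In diffuse large B-cell lymphoma (DLBCL), baseline FDG PET/CT captures not
only how much tumor a patient carries but also how widely it has spread.
Total metabolic tumor volume (TMTV, the summed volume of all segmented
lesions) is an established prognostic factor, and purely inter-lesion
dissemination distances such as Dmax (largest centroid-to-centroid distance
between any two lesions) and Dbulk (largest distance from the biggest
lesion to any other) add further signal. This package implements a family
of *organ-referenced* dissemination biomarkers that anchor the geometry to
the spleen, the lymphatic system's reference organ:

* **SpreadSpleen** — the population standard deviation of the distances
  from the spleen centroid to every lesion centroid,
  $\sigma = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N} (\|AB_i\| - \mu)^2}$ with
  $\mu = \tfrac{1}{N}\sum_i \|AB_i\|$, where $A$ is the spleen centroid and
  $B_i$ the centroid of lesion $i$;
* **Dspleen** — the distance from the spleen centroid to the farthest
  lesion centroid, $\max_i \|AB_i\|$;
* **sDspleen** — Dspleen divided by body surface area (Mosteller,
  $\mathrm{BSA} = \sqrt{w_{\mathrm{kg}} \cdot h_{\mathrm{cm}}}/60$ m²),
  reported ×100 in m⁻¹.

Unlike Dmax and Dbulk, which are identically zero for single-lesion
patients, the spleen-referenced family is defined for every patient,
including those with one lesion (SpreadSpleen is then 0 and Dspleen is that
lesion's distance). Because the features depend only on the organ
*centroid*, they are insensitive to the exact organ delineation — a
property the package probes directly (see the robustness experiment
below).

All geometry is computed in physical millimeters through the NIfTI affine,
with the voxel-center convention; distances are reported in cm, volumes in
cm³, and sDspleen in m⁻¹ with the conventional ×100 presentation column.
The conversion constants live in one internal table.

A note on the BSA formula: the Mosteller form divides the square root of
weight × height by 60. Some renderings of this formula omit the square
root; the package deliberately uses the square-root form, which produces
physiologically sensible areas (for the reference adult of 72 kg and
168 cm, 1.833 m²).

## Segmentation quality control

The spleen mask is expected to come from an automatic segmenter. Two
screens trigger a warning:

1. **Single connected component.** A spleen should be one blob. If the
   mask has several components, the largest is kept automatically
   (satellites are typically segmentation spillover) and the case is
   flagged `MULTI_COMPONENT` with `auto_corrected = TRUE`. The correction
   is idempotent and can only shrink the mask.
2. **Field-of-view containment.** A spleen partially outside the body
   field of view cannot be fixed geometrically; the case is flagged
   `OUT_OF_FOV` with `needs_manual_review = TRUE` and excluded from
   downstream stages until a replacement mask is supplied. The containment
   threshold is a design choice, not a published criterion: we require at
   least 95% of spleen voxels inside the region, and default the region to
   the full image grid when no body mask is given. Empty masks are flagged
   `EMPTY`.

Voxel connectivity defaults to 26 (faces, edges and corners). This is the
most permissive convention and avoids spurious multi-component warnings
from one-voxel-thin necks; it is configurable (6/18/26) because lesion
splitting in `connected_components` mode uses the same machinery. The
production component labeling is built on an adjacency graph (igraph); the
test suite checks it exactly against an independent breadth-first flood
fill on random sparse masks.

## Feature extraction choices

* **Centroids are unweighted.** The centroid of a mask is the plain mean
  of its member voxel centers. No PET-intensity weighting is applied —
  uptake-weighted centroids would require SUV data, which is out of scope.
* **Lesion identity.** Expert masks usually carry one integer label per
  lesion (`per_label` mode, the default). Binary masks fall back to
  `connected_components` mode. The mode changes the lesion count N and is
  recorded in the output metadata.
* **Dbulk tie-break.** "Largest lesion" means largest by volume; volume
  ties resolve to the lowest lesion id, so outputs are deterministic.
* **Splenic invasion.** A boolean flag: any lesion voxel overlapping any
  spleen voxel. Lesions inside the spleen stay in the distance lists; the
  invasion flag supports subgroup re-runs (`subgroup_run`), which let the
  user verify that the spleen-referenced features carry signal beyond mere
  invasion.
* **Grid alignment is a hard error.** Lesion and organ masks must share
  shape and affine to 10⁻³ mm. Nearest-neighbor resampling exists but is
  opt-in (`allow_resample`), because silent resampling can shift centroids
  by up to a voxel.

## Survival protocol

The statistical layer mirrors a standard prognostic-biomarker workflow:

* **Cutoffs** — sample median by default; a Youden-optimal cutoff
  (maximizing sensitivity + specificity − 1 of the censoring-weighted
  cumulative/dynamic ROC at a horizon) as an alternative; fixed published
  values (e.g. TMTV 220 cm³) for three-group stratification. Youden ties
  resolve to the lowest qualifying threshold.
* **Kaplan–Meier / log-rank** via the survival package. With no events the
  log-rank statistic is reported as NA, never silently.
* **Cox models** by maximum partial likelihood with Efron tie handling
  (the standard, small-sample-robust default). Continuous covariates enter
  on their natural scale with the ×100 sDspleen convention; dichotomized
  coding is available through the cutoff rules. Non-convergence is
  reported in the result.
* **Harrell concordance** via `survival::concordance` (higher risk =
  shorter survival), checked in the tests against exhaustive pair
  enumeration.
* **Time-dependent AUC.** No installed package provides a
  censoring-weighted time-dependent ROC, so the package implements the
  inverse-probability-of-censoring-weighted cumulative/dynamic estimator:
  cases are patients with an event by the horizon (weighted by
  $1/\hat G(T_i^-)$, with $\hat G$ the Kaplan–Meier estimate of the
  censoring distribution), controls are patients event-free past it
  (weighted by $1/\hat G(t)$). The default horizon is 48 months,
  echoing the 4-year outcome window common in DLBCL trials; it is
  configurable because published analyses rarely state their horizon.
* **Bootstrap CIs.** Every reported hazard ratio, concordance and AUC
  carries an empirical 95% CI from a patient-level bootstrap (resampling
  rows with replacement). The reference protocol uses 5,000 resamples; the
  count is configurable and scaled-down runs (200–1,000) are used in the
  test suite. If the statistic fails on more than 5% of resamples the
  bootstrap aborts rather than report a biased interval.
* **Concordance gain.** Whether adding a feature to a base Cox model
  improves discrimination is tested by a *paired* bootstrap: both models
  are refit on each resample and the difference of concordances recorded;
  the two-sided p-value is proportion-based with a +1 continuity
  correction. The identity extension returns ΔC = 0, p = 1 by
  construction.
* **Multiple testing.** None applied; raw p-values are reported, matching
  common practice for exploratory biomarker panels. Users comparing many
  features should adjust externally.

## The synthetic cohort generator

No public dataset pairs expert lesion masks with organ masks and survival,
so validation rests on phantoms with known ground truth. The generator
emulates:

* a body ellipsoid (semi-axes 145 × 105 × 145 mm) on a 96³ grid at 4 mm
  isotropic spacing, sized so every lesion sphere always fits the grid;
* an ellipsoidal spleen (nominal semi-axes 30 × 40 × 50 mm ≈ 251 cm³,
  near the median adult spleen volume; per-patient 0.85–1.15× jitter) at a
  fixed left-upper-quadrant offset of the body center, so liver-style
  alternative reference organs remain geometrically meaningful;
* 1 + Poisson(4) spherical lesions placed uniformly in the body ellipsoid,
  with log-normal radii (median 17 mm, σ_log 0.5, clamped to 6–40 mm) —
  positions independent of volumes by construction, so distance features
  decorrelate from TMTV up to the shared dependence on lesion count;
* clinical covariates: weight ~ N(73, 12²) kg, height ~ N(168, 10²) cm
  (truncated), age-adjusted IPI sampled from {1, 2, 3} with probabilities
  0.35/0.45/0.20;
* survival: progression times from a Weibull baseline (shape 1.2, scale
  140 months) scaled by exp of a linear predictor over the standardized
  true features (defaults: 0.4 per SD of TMTV, 0.7 per SD of Dspleen,
  0.25 per IPI step), inverted in closed form through the Weibull
  cumulative hazard; death adds an exponential post-progression survival
  (mean 30 months), which guarantees PFS ≤ OS; independent exponential
  censoring (rate 1/240 per month) plus an administrative 84-month
  horizon. The scale was calibrated once, by direct Monte Carlo of these
  laws, so that roughly a quarter of patients have an observed
  progression event within 48 months under the default effect sizes.

Lesions are spheres because only centroids and volumes matter downstream;
the spleen is an ellipsoid so its centroid differs from any bounding-box
center. Shapes are digitized by the voxel-center inclusion test, making a
spec map deterministically to voxel data; when two lesion spheres claim a
voxel the higher label wins and the reassignment count is recorded.

`simulate_cohort` computes features analytically from the drawn geometry
by default and renders voxel phantoms on request (`render = TRUE`). The
analytic path exists because the package's own validation experiments run
hundreds of simulated cohorts, which would be pointlessly slow through
voxelization; the equivalence of the two paths — centroids within a voxel
diagonal, volumes within digitization error — is itself a tested
invariant, as is the exact seed-determinism of the whole generator.

What the generator does *not* emulate: PET intensities and texture,
scanner noise and partial-volume effects, non-spherical or confluent
lesion shapes, anatomically realistic organ placement, or correlations
between lesion geometry and clinical covariates. Passing tests therefore
demonstrate that the geometry, QC and statistical machinery are correct
and calibrated — not that the biomarkers are prognostic in real patients.
The approximate analytic invasion flag (lesion center inside the spleen
ellipsoid dilated by the lesion radius) is exact for spheres against a
sphere and a close bound against the mild spleen anisotropy used here.

## Numerical and degenerate-input conventions

* Voxel labels must be integers; values within 10⁻⁶ of an integer are
  rounded, anything else is rejected.
* Empty lesion volumes are an error (no features exist); empty spleen
  masks are a reportable QC outcome.
* Single-lesion patients: spread = 0, Dmax = Dbulk = 0, Dspleen = that
  lesion's distance.
* Missing weight or height: BSA and sDspleen are NA and flagged; Dspleen
  stands in. Patients missing a stratification feature are excluded with a
  message, never silently.
* All stochastic procedures (bootstrap, perturbation, simulation) take
  explicit integer seeds, restore the caller's RNG state, and embed the
  seed in their outputs; pipeline re-runs with identical configs are
  byte-identical.

## Problem sizes used in validation

The test suite validates geometry against brute-force oracles on 200
random configurations, component labeling against flood fill on 100 random
masks, and the statistical layer on simulated cohorts: 50 cohorts of
n = 300 with 500-resample bootstraps for log-hazard-ratio recovery,
500 cohorts of n = 200 for null calibration of the log-rank test and
concordance, and 2 × 50 cohorts of n = 300 with 200-resample paired
bootstraps for the concordance-gain test. The bundled acceptance script
runs one n = 300 cohort end-to-end plus a rendered n = 100 subcohort for
the 2-cm perturbation experiment. These sizes are scaled-down analogues of
a ~300-patient clinical cohort analysed with 5,000-resample bootstraps;
the protocol itself is identical.

## Known limitations

* The spleen segmentation model itself is out of scope: masks are consumed
  as files, and the QC stage is the only guard against bad ones.
* DICOM ingestion, SUV quantification and registration estimation are not
  provided; inputs must be co-registered NIfTI label volumes.
* The time-dependent AUC estimator is the IPCW cumulative/dynamic form;
  other estimators (incident/dynamic, Heagerty–Zheng smoothing) would give
  somewhat different values and are not implemented.
* Pearson correlations on heavy-tailed features (TMTV) are
  outlier-sensitive; the decorrelation checks report achieved values
  rather than asserting tight bounds on single cohorts.
* Whether multivariate hazard ratios should use continuous or dichotomized
  covariates is a genuine ambiguity in published analyses; both codings
  are available and neither is privileged.
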