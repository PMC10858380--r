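# lesiondist

Spleen-referenced tumor dissemination biomarkers for lymphoma PET/CT, with
segmentation quality control, a full survival-analysis protocol, and a
synthetic phantom cohort generator for validation.

## What it computes, and for whom

In diffuse large B-cell lymphoma (DLBCL), how widely the disease has
disseminated at baseline carries prognostic information beyond total tumor
burden. Given per-patient co-registered NIfTI label volumes — an
expert-delineated lesion mask and an automatically segmented reference
organ mask (spleen by default; liver or bladder as alternatives) — plus a
clinical CSV, the package computes:

* **TMTV** (cm³): total metabolic tumor volume, the sum of lesion volumes;
* **Dmax** (cm): largest centroid-to-centroid distance between any two
  lesions; **Dbulk** (cm): largest distance from the biggest lesion's
  centroid to any other;
* **SpreadSpleen** (cm): the population SD of spleen-centroid-to-lesion
  distances, `σ = sqrt(Σ(‖ABᵢ‖ − μ)² / N)`;
* **Dspleen** (cm): distance from the spleen centroid to the farthest
  lesion; **sDspleen** (m⁻¹, reported ×100): Dspleen normalized by
  Mosteller body surface area `sqrt(weight_kg × height_cm)/60`;
* a **splenic invasion** flag and the spleen volume.

Around the features sit: quality control for the organ mask (single
connected component, field-of-view containment, largest-component
auto-correction), and the survival protocol — median/Youden/fixed cutoffs,
Kaplan–Meier with log-rank tests, two- and three-group risk
stratification (TMTV 220 cm³ + a dissemination feature), univariate and
multivariate Cox models with Efron ties, Harrell concordance,
censoring-weighted time-dependent AUC, patient-level bootstrap confidence
intervals, and a paired-bootstrap test for the concordance gained by
adding a feature to a base model.

It is aimed at imaging and biostatistics researchers evaluating
dissemination biomarkers, and at anyone needing a tested, reproducible
reference implementation of this feature family.

## Worked example

Feature math on analytic centroids (spleen centroid at the origin, lesions
at (30, 0, 0) mm with 10 cm³ and (0, 40, 0) mm with 2 cm³):

```r
library(lesiondist)

ls  <- lesion_set(data.frame(lesion_id = 1:2, cx = c(30, 0), cy = c(0, 40),
                             cz = c(0, 0), volume_cm3 = c(10, 2)))
ref <- reference_point(c(0, 0, 0), organ = "spleen")
features_from_geometry(ls, ref, bsa_m2 = body_surface_area(72, 168),
                       patient_id = "P001")
#>   patient_id n_lesions tmtv_cm3 spread_cm d_ref_cm sd_ref_x100 dmax_cm dbulk_cm
#> 1       P001         2       12       0.5        4    2.182179       5        5
```

The two distances are 30 and 40 mm, so SpreadSpleen is their population SD
(5 mm = 0.5 cm), Dspleen the maximum (4 cm), and Dmax = Dbulk = 5 cm by
the 3-4-5 triangle. On real data you would instead call
`extract_features(patient, lesion_vol, organ_mask)` on volumes from
`read_label_volume()`, after `qc_spleen()`.

A simulated 300-patient cohort through the survival protocol:

```r
co  <- simulate_cohort(cohort_spec(n_patients = 300, seed = 1))
tab <- merge(co$features, co$clinical, by = "patient_id")
rep <- fit_survival_report(tab, covariates = c("tmtv_cm3", "d_ref_cm"),
                           n_resamples = 500, seed = 1)
rep$univariate[, c("feature", "hr", "c_index", "td_auc", "cutoff", "logrank_p")]
#>    feature   hr c_index td_auc cutoff logrank_p
#> 1 tmtv_cm3 1.00   0.651  0.684  217.5  4.99e-05
#> 2 d_ref_cm 1.28   0.680  0.694   20.5  6.92e-08
```

The generator plants a true log-hazard ratio of 0.7 per SD of Dspleen
(`d_ref_cm`) and 0.4 per SD of TMTV; both features split the cohort
significantly at their median cutoffs (`logrank_p`), the per-unit hazard
ratios carry bootstrap CIs in the full report, and concordance/AUC sit in
the 0.65–0.70 range expected for effects of this size. TMTV's hazard
ratio prints as 1.00 because it is per cm³ of a feature spanning hundreds
of cm³.

A command-line front end wrapping the same functions lives at
`inst/cli/lesiondist.R` (subcommands `simulate`, `qc-spleen`,
`extract-features`, `survival`, `run-all`, `robustness`).

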