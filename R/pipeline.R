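#' Configure an end-to-end pipeline run
#'
#' Bundles every knob of a reproducible run: input manifests, reference
#' organ, QC and feature-extraction settings, survival protocol and seed.
#' The manifest CSV must have columns `patient_id`, `lesion_mask`,
#' `organ_mask` and optionally `body_mask` (paths to NIfTI files).
#'
#' @param manifest path to the manifest CSV.
#' @param clinical path to the clinical CSV (see [read_clinical_table]).
#' @param output_dir directory for run artifacts (created if needed).
#' @param organ reference organ tag.
#' @param mode lesion identity mode, see [lesion_centroids].
#' @param connectivity voxel connectivity.
#' @param fov_threshold QC containment threshold.
#' @param covariates feature columns entering the survival models.
#' @param endpoints subset of `"PFS"`, `"OS"`.
#' @param horizon time-dependent AUC horizon, months.
#' @param n_bootstrap bootstrap resamples for CIs.
#' @param cutoff_rules optional named list of [cutoff_rule]s.
#' @param allow_resample resample misaligned masks (nearest neighbor)
#'   instead of failing? Off by default: silent resampling can shift
#'   centroids.
#' @param seed integer seed (mandatory: every stochastic stage uses it).
#' @return a `run_config` list.
#' @export
run_config <- function(manifest, clinical, output_dir,
                       organ = "spleen", mode = "per_label",
                       connectivity = 26, fov_threshold = 0.95,
                       covariates = c("tmtv_cm3", "spread_cm", "d_ref_cm",
                                      "sd_ref_x100"),
                       endpoints = c("PFS", "OS"), horizon = 48,
                       n_bootstrap = 5000, cutoff_rules = NULL,
                       allow_resample = FALSE, seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(manifest = manifest, clinical = clinical,
                 output_dir = output_dir, organ = organ, mode = mode,
                 connectivity = connectivity,
                 fov_threshold = fov_threshold, covariates = covariates,
                 endpoints = match.arg(endpoints, several.ok = TRUE),
                 horizon = horizon, n_bootstrap = n_bootstrap,
                 cutoff_rules = cutoff_rules,
                 allow_resample = allow_resample,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Canonical JSON of a config (rules flattened), and its md5 hash. The hash
# ties every output file to the exact configuration that produced it.
config_json <- function(config) {
  x <- unclass(config)
  x$cutoff_rules <- lapply(x$cutoff_rules, unclass)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, null = "null")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(config_json(config)), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline: QC, feature extraction, survival analysis
#'
#' Executes the three stages over every patient in the manifest and writes
#' `qc_report.csv`, `features.csv`, `lesions.csv`, `survival_report.json`
#' and `provenance.json` (config hash, package version, seed, exclusions,
#' output checksums) into the configured output directory. Patients whose
#' spleen QC demands manual review are excluded from features and survival
#' and listed explicitly in the QC report and provenance, never silently
#' dropped. Re-running with an identical config reproduces all CSV/JSON
#' outputs byte for byte. Any stage failure halts the run naming the
#' patient and stage.
#'
#' @param config a [run_config].
#' @param quiet suppress per-patient progress messages?
#' @return invisibly, a list with `output_dir`, `qc`, `features`, `lesions`,
#'   `refs`, `clinical`, `survival` (per-endpoint reports), `exclusions`
#'   and `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
  need <- c("patient_id", "lesion_mask", "organ_mask")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  clinical <- read_clinical_table(config$clinical)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  qc_rows <- list(); feat_rows <- list(); lesion_rows <- list()
  refs <- list(); exclusions <- character(0)

  process_patient <- function(i, stage_env) {
    pid <- man$patient_id[i]
    stage_env$stage <- "qc"
    for (col in c("lesion_mask", "organ_mask"))
      if (!file.exists(man[[col]][i]))
        stop("missing file: ", man[[col]][i])
    lesion_vol <- read_label_volume(man$lesion_mask[i])
    organ_mask <- read_label_volume(man$organ_mask[i])
    if (!check_grid_alignment(lesion_vol, organ_mask)$aligned) {
      if (!config$allow_resample)
        stop("masks on different grids (set allow_resample to recover)")
      organ_mask <- resample_labels_nearest(organ_mask, lesion_vol)
    }
    has_body <- "body_mask" %in% names(man) &&
      !is.na(man$body_mask[i]) && nzchar(man$body_mask[i])
    fov <- if (has_body)
      body_fov_mask(organ_mask,
                    body_mask = read_label_volume(man$body_mask[i]))
    else body_fov_mask(organ_mask)
    qc <- qc_spleen(organ_mask, fov = fov,
                    connectivity = config$connectivity,
                    fov_threshold = config$fov_threshold,
                    patient_id = pid)
    if (qc$report$needs_manual_review) {
      say("[qc] ", pid, ": needs manual review (",
          qc$report$warning_reasons, "); excluded")
      return(list(qc = qc$report, excluded = TRUE))
    }
    if (qc$report$warning)
      say("[qc] ", pid, ": ", qc$report$warning_reasons,
          " (auto-corrected)")
    stage_env$stage <- "features"
    patient <- clinical[clinical$patient_id == pid, , drop = FALSE]
    if (nrow(patient) == 0L)
      stop("patient not present in clinical table")
    lesions <- lesion_centroids(lesion_vol, mode = config$mode,
                                connectivity = config$connectivity,
                                patient_id = pid)
    ref <- reference_centroid(qc$mask, organ = config$organ)
    bsa <- if (patient$bsa_available)
      body_surface_area(patient$weight_kg, patient$height_cm) else NA_real_
    fv <- features_from_geometry(
      lesions, ref, bsa_m2 = bsa, patient_id = pid,
      organ_volume_cm3 = organ_volume(qc$mask),
      invasion = splenic_invasion(lesion_vol, qc$mask))
    list(qc = qc$report, excluded = FALSE, fv = fv,
         lesions = cbind(patient_id = pid, as.data.frame(lesions)),
         ref = ref)
  }

  for (i in seq_len(nrow(man))) {
    pid <- man$patient_id[i]
    stage_env <- new.env(parent = emptyenv())
    stage_env$stage <- "qc"
    res <- tryCatch(process_patient(i, stage_env), error = function(e) {
      stop("pipeline failed at stage '", stage_env$stage,
           "' for patient '", pid, "': ", conditionMessage(e),
           call. = FALSE)
    })
    qc_rows[[pid]] <- res$qc
    if (res$excluded) {
      exclusions <- c(exclusions, pid)
    } else {
      feat_rows[[pid]] <- res$fv
      lesion_rows[[pid]] <- res$lesions
      refs[[pid]] <- res$ref
    }
  }

  qc_df <- do.call(rbind, unname(qc_rows))
  features <- do.call(rbind, unname(feat_rows))
  lesions_df <- do.call(rbind, unname(lesion_rows))
  rownames(qc_df) <- rownames(features) <- rownames(lesions_df) <- NULL
  if (is.null(features) || nrow(features) == 0L)
    stop("no patient survived QC; nothing to analyze")

  stage_tab <- merge(features, clinical, by = "patient_id", sort = TRUE)
  surv <- list()
  covs <- intersect(config$covariates, names(stage_tab))
  covs <- covs[vapply(covs, function(cv)
    sum(stats::complete.cases(stage_tab[[cv]])) > 0 &&
      stats::sd(stage_tab[[cv]], na.rm = TRUE) > 0, logical(1))]
  for (ep in config$endpoints) {
    tc <- if (ep == "PFS") "pfs_months" else "os_months"
    ec <- if (ep == "PFS") "pfs_event" else "os_event"
    surv[[ep]] <- fit_survival_report(
      stage_tab, covariates = covs, time_col = tc, event_col = ec,
      endpoint = ep, horizon = config$horizon,
      cutoff_rules = config$cutoff_rules,
      n_resamples = config$n_bootstrap, seed = config$seed)
  }

  out <- config$output_dir
  utils::write.csv(qc_df, file.path(out, "qc_report.csv"),
                   row.names = FALSE)
  utils::write.csv(features, file.path(out, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(lesions_df, file.path(out, "lesions.csv"),
                   row.names = FALSE)
  surv_json <- lapply(surv, function(r) unclass(r))
  jsonlite::write_json(surv_json, file.path(out, "survival_report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)

  artifacts <- c("qc_report.csv", "features.csv", "lesions.csv",
                 "survival_report.json")
  prov <- list(
    config = jsonlite::fromJSON(as.character(config_json(config))),
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("lesiondist")),
    seed = config$seed,
    exclusions = as.list(exclusions),
    checksums = as.list(tools::md5sum(file.path(out, artifacts)))
  )
  names(prov$checksums) <- artifacts
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  invisible(list(output_dir = out, qc = qc_df, features = features,
                 lesions = lesions_df, refs = refs, clinical = clinical,
                 survival = surv, exclusions = exclusions,
                 config = config))
}

#' Write a simulated cohort to disk as pipeline inputs
#'
#' Renders each patient's phantoms to NIfTI and writes the clinical CSV and
#' a manifest CSV, producing exactly the on-disk layout [run_pipeline]
#' consumes. The cohort spec is written alongside as JSON for provenance.
#'
#' @param cohort a rendered [simulate_cohort] result (`render = TRUE`).
#' @param dir output directory.
#' @return path to the directory, invisibly; `manifest.csv`,
#'   `clinical.csv`, `cohort_spec.json` and one NIfTI pair per patient are
#'   created inside.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_sim"))
  if (is.null(cohort$phantoms))
    stop("cohort was simulated without phantom rendering; ",
         "re-run simulate_cohort(spec, render = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$phantoms)
  lesion_paths <- file.path(dir, paste0(ids, "_lesions.nii.gz"))
  organ_paths <- file.path(dir, paste0(ids, "_spleen.nii.gz"))
  for (i in seq_along(ids)) {
    write_label_volume(cohort$phantoms[[i]]$lesions, lesion_paths[i])
    write_label_volume(cohort$phantoms[[i]]$spleen, organ_paths[i])
  }
  utils::write.csv(data.frame(patient_id = ids,
                              lesion_mask = lesion_paths,
                              organ_mask = organ_paths),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  spec <- cohort$spec
  jsonlite::write_json(unclass(spec), file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(dir)
}

#' Reference-centroid perturbation robustness experiment
#'
#' Probes the sensitivity of the spleen-referenced features to the exact
#' organ delineation: in each repeat, every patient's reference centroid is
#' displaced by exactly `radius_cm` in an independent uniformly random
#' direction, the spleen-based features are recomputed from the stored
#' lesion centroids, and the configured univariate models are refit. By the
#' triangle inequality each per-patient distance feature can move by at
#' most `radius_cm`.
#'
#' @param run result of [run_pipeline] (features previously extracted).
#' @param radius_cm displacement radius, cm (default 2).
#' @param n_repeats number of perturbation repeats.
#' @param seed integer seed.
#' @param time_col,event_col endpoint used for the refits.
#' @return list with `per_patient` (per repeat/patient feature deltas, cm
#'   and 1/m x100), `c_index` (per repeat/feature concordance vs baseline)
#'   and the experiment parameters.
#' @export
robustness_experiment <- function(run, radius_cm = 2, n_repeats = 10,
                                  seed = 1L, time_col = "pfs_months",
                                  event_col = "pfs_event") {
  stopifnot(radius_cm >= 0, n_repeats >= 1)
  feats <- run$features
  tab0 <- merge(feats, run$clinical, by = "patient_id", sort = TRUE)
  spleen_covs <- intersect(c("spread_cm", "d_ref_cm", "sd_ref_x100"),
                           run$config$covariates)
  base_c <- vapply(spleen_covs, function(cv) {
    d <- tab0[stats::complete.cases(tab0[, c(cv, time_col, event_col)]), ]
    cox_model(d[, cv, drop = FALSE], d[[time_col]], d[[event_col]])$c_index
  }, numeric(1))

  ids <- feats$patient_id
  per_patient <- list(); cidx <- list()
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      new_feats <- feats
      for (pid in ids) {
        ref <- run$refs[[pid]]
        pref <- perturb_reference(ref, radius_cm)
        ls <- run$lesions[run$lesions$patient_id == pid, , drop = FALSE]
        lset <- lesion_set(ls[, c("lesion_id", "cx", "cy", "cz",
                                  "volume_cm3")],
                           patient_id = pid)
        d_mm <- distances_to_reference(pref, lset)
        j <- which(new_feats$patient_id == pid)
        bsa <- new_feats$bsa_m2[j]
        new_feats$spread_cm[j] <- spread(d_mm)
        new_feats$d_ref_cm[j] <- d_reference(d_mm)
        sdr <- if (is.finite(bsa) && bsa > 0)
          standardized_distance(new_feats$d_ref_cm[j], bsa) else NA_real_
        new_feats$sd_ref_m1[j] <- sdr
        new_feats$sd_ref_x100[j] <- 100 * sdr
      }
      per_patient[[r]] <- data.frame(
        repeat_id = r, patient_id = ids,
        delta_spread_cm = new_feats$spread_cm - feats$spread_cm,
        delta_d_ref_cm = new_feats$d_ref_cm - feats$d_ref_cm,
        delta_sd_ref_x100 = new_feats$sd_ref_x100 - feats$sd_ref_x100)
      tab <- merge(new_feats, run$clinical, by = "patient_id", sort = TRUE)
      cidx[[r]] <- do.call(rbind, lapply(spleen_covs, function(cv) {
        d <- tab[stats::complete.cases(tab[, c(cv, time_col, event_col)]), ]
        cc <- cox_model(d[, cv, drop = FALSE], d[[time_col]],
                        d[[event_col]])$c_index
        data.frame(repeat_id = r, feature = cv, c_index = cc,
                   c_baseline = base_c[[cv]], delta = cc - base_c[[cv]])
      }))
    }
  })
  list(per_patient = do.call(rbind, per_patient),
       c_index = do.call(rbind, cidx),
       radius_cm = radius_cm, n_repeats = n_repeats, seed = seed)
}
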