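#' Lesion centroids and volumes from a labeled lesion volume
#'
#' Each lesion is summarized by the unweighted geometric centroid of its
#' member voxel centers (physical mm) and its volume (voxel count times
#' voxel volume, cm^3). In `per_label` mode (default for expert masks, which
#' carry one label per lesion) every distinct positive label is one lesion;
#' in `connected_components` mode the binarized foreground is split into
#' lesions by voxel connectivity, for masks delivered without labels. The
#' mode changes the lesion count N and is recorded on the result.
#'
#' @param lesion_vol a non-empty [label_volume].
#' @param mode `"per_label"` or `"connected_components"`.
#' @param connectivity used in `connected_components` mode.
#' @param patient_id optional id carried on the result.
#' @return A `lesion_set`: data.frame with columns `lesion_id`, `cx`, `cy`,
#'   `cz` (mm) and `volume_cm3`, ordered by `lesion_id`, with attributes
#'   `patient_id` and `mode`.
#' @export
lesion_centroids <- function(lesion_vol,
                             mode = c("per_label", "connected_components"),
                             connectivity = 26, patient_id = NA_character_) {
  mode <- match.arg(mode)
  if (sum(lesion_vol$voxels > 0L) == 0L)
    stop("lesion volume is empty; no features can be computed")
  if (mode == "connected_components") {
    cc <- connected_components(lesion_vol, connectivity = connectivity)
    vox <- cc$labels
  } else {
    vox <- lesion_vol$voxels
  }
  idx <- which(vox > 0L)
  labs <- vox[idx]
  ijk <- arrayInd(idx, dim(vox)) - 1L
  world <- voxel_to_world(lesion_vol, ijk)
  counts <- as.vector(rowsum(rep(1, length(labs)), labs))
  sums <- rowsum(world, labs)
  ids <- sort(unique(labs))
  out <- data.frame(
    lesion_id = as.integer(ids),
    cx = sums[, 1] / counts,
    cy = sums[, 2] / counts,
    cz = sums[, 3] / counts,
    volume_cm3 = mm3_to_cm3(counts * voxel_volume_mm3(lesion_vol))
  )
  out <- out[order(out$lesion_id), , drop = FALSE]
  rownames(out) <- NULL
  lesion_set(out, patient_id = patient_id, mode = mode)
}

#' Construct a lesion set from centroid/volume data
#' @param df data.frame with columns `lesion_id`, `cx`, `cy`, `cz` (mm),
#'   `volume_cm3`.
#' @param patient_id,mode metadata attributes.
#' @return the validated data.frame with class `lesion_set`.
#' @export
lesion_set <- function(df, patient_id = NA_character_, mode = "analytic") {
  need <- c("lesion_id", "cx", "cy", "cz", "volume_cm3")
  if (!all(need %in% names(df)))
    stop("lesion set needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$lesion_id)) stop("lesion_id values must be unique")
  if (any(df$volume_cm3 <= 0)) stop("lesion volumes must be > 0")
  df <- df[order(df$lesion_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, patient_id = patient_id, mode = mode,
            class = c("lesion_set", "data.frame"))
}

#' Centroid of a reference organ
#'
#' The unweighted mean of the foreground voxel centers in physical mm. This
#' point anchors the spleen-referenced distance features; because it is a
#' centroid, it is barely sensitive to the precise organ delineation.
#'
#' @param organ_mask a QC-passed, non-empty [label_volume].
#' @param organ tag: `"spleen"`, `"liver"`, `"bladder"` or `"custom"`.
#' @return A `reference_point`: list with `organ` and `centroid` (mm).
#' @export
reference_centroid <- function(organ_mask,
                               organ = c("spleen", "liver", "bladder",
                                         "custom")) {
  organ <- match.arg(organ)
  ijk <- foreground_indices(organ_mask)
  if (nrow(ijk) == 0L) stop("organ mask is empty")
  world <- voxel_to_world(organ_mask, ijk)
  reference_point(colMeans(world), organ = organ)
}

#' Construct a reference point from coordinates
#' @param centroid length-3 numeric, physical mm.
#' @param organ organ tag.
#' @return a `reference_point`.
#' @export
reference_point <- function(centroid, organ = "spleen") {
  centroid <- as.numeric(centroid)
  stopifnot(length(centroid) == 3L, all(is.finite(centroid)))
  structure(list(organ = organ, centroid = centroid),
            class = "reference_point")
}

#' Euclidean distances from a reference point to each lesion centroid
#' @param ref a `reference_point`.
#' @param lesions a `lesion_set`.
#' @return numeric vector of distances in mm, one per lesion, in lesion
#'   order.
#' @export
distances_to_reference <- function(ref, lesions) {
  stopifnot(inherits(ref, "reference_point"), nrow(lesions) >= 1L)
  dx <- lesions$cx - ref$centroid[1]
  dy <- lesions$cy - ref$centroid[2]
  dz <- lesions$cz - ref$centroid[3]
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Lesion spread relative to a reference organ
#'
#' The population standard deviation (divide by N, not N - 1) of the
#' reference-to-lesion centroid distances, reported in cm. With the spleen
#' as reference this is the SpreadSpleen biomarker. Defined for any N >= 1;
#' a single lesion gives spread 0.
#'
#' @param distances_mm distances from [distances_to_reference], in mm.
#' @return spread in cm.
#' @export
spread <- function(distances_mm) {
  if (length(distances_mm) == 0L) stop("empty distance list")
  mu <- mean(distances_mm)
  mm_to_cm(sqrt(mean((distances_mm - mu)^2)))
}

#' Distance to the farthest lesion from the reference organ
#'
#' With the spleen as reference this is the Dspleen biomarker. Defined for
#' any N >= 1.
#'
#' @inheritParams spread
#' @return maximum distance in cm.
#' @export
d_reference <- function(distances_mm) {
  if (length(distances_mm) == 0L) stop("empty distance list")
  mm_to_cm(max(distances_mm))
}

#' Body surface area (Mosteller)
#'
#' `sqrt(weight_kg * height_cm) / 60`, in m^2.
#'
#' @param weight_kg body weight, kg (> 0).
#' @param height_cm body height, cm (> 0).
#' @return body surface area in m^2.
#' @export
body_surface_area <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive and finite")
  sqrt(weight_kg * height_cm) / 60
}

#' Standardized reference distance
#'
#' The farthest-lesion distance divided by body surface area, in 1/m. With
#' the spleen as reference this is sDspleen. Reports conventionally carry
#' the value scaled by 100 (column `sd_ref_x100`), which this function does
#' not apply.
#'
#' @param d_ref_cm farthest-lesion distance, cm.
#' @param bsa_m2 body surface area, m^2.
#' @return standardized distance in 1/m.
#' @export
standardized_distance <- function(d_ref_cm, bsa_m2) {
  if (any(!is.finite(bsa_m2)) || any(bsa_m2 <= 0))
    stop("body surface area must be positive; mark the feature missing ",
         "and fall back to the unstandardized distance instead")
  cm_to_m(d_ref_cm) / bsa_m2
}

#' Maximal inter-lesion distance (Dmax)
#'
#' Largest centroid-to-centroid Euclidean distance over all lesion pairs,
#' in cm; 0 for a single lesion.
#'
#' @param lesions a `lesion_set`.
#' @return Dmax in cm.
#' @export
dmax <- function(lesions) {
  if (nrow(lesions) == 0L) stop("empty lesion set")
  dmax_points(as.matrix(lesions[, c("cx", "cy", "cz")]))
}

# Point-matrix core shared with the cohort generator's analytic path.
dmax_points <- function(xyz) {
  if (nrow(xyz) == 1L) return(0)
  mm_to_cm(max(stats::dist(xyz)))
}

dbulk_points <- function(xyz, volumes) {
  if (nrow(xyz) == 1L) return(0)
  bulk <- which.max(volumes)  # rows in lesion_id order: tie -> lowest id
  dx <- xyz[, 1] - xyz[bulk, 1]
  dy <- xyz[, 2] - xyz[bulk, 2]
  dz <- xyz[, 3] - xyz[bulk, 3]
  mm_to_cm(max(sqrt(dx^2 + dy^2 + dz^2)))
}

#' Bulk-lesion distance (Dbulk)
#'
#' Maximum distance from the centroid of the largest lesion (by volume; ties
#' broken by the lowest lesion_id, so the result is deterministic) to any
#' other lesion centroid, in cm; 0 for a single lesion. Always <= Dmax.
#'
#' @param lesions a `lesion_set`.
#' @return Dbulk in cm.
#' @export
dbulk <- function(lesions) {
  if (nrow(lesions) == 0L) stop("empty lesion set")
  dbulk_points(as.matrix(lesions[, c("cx", "cy", "cz")]),
               lesions$volume_cm3)
}

#' Total metabolic tumor volume (TMTV)
#' @param lesions a `lesion_set`.
#' @return sum of lesion volumes, cm^3.
#' @export
tmtv <- function(lesions) {
  if (nrow(lesions) == 0L) stop("empty lesion set")
  sum(lesions$volume_cm3)
}

#' Splenic invasion flag
#'
#' TRUE iff any lesion foreground voxel coincides with a spleen foreground
#' voxel. Requires the two masks to share a grid (hard error otherwise:
#' voxelwise overlap is meaningless across grids).
#'
#' @param lesion_vol lesion [label_volume].
#' @param spleen_mask spleen [label_volume] on the same grid.
#' @return logical.
#' @export
splenic_invasion <- function(lesion_vol, spleen_mask) {
  stop_if_misaligned(lesion_vol, spleen_mask, what = "lesion and spleen masks")
  any(lesion_vol$voxels > 0L & spleen_mask$voxels > 0L)
}

#' Randomly displace a reference point by a fixed radius
#'
#' Robustness probe: the centroid is moved by exactly `radius_cm` in a
#' uniformly random 3D direction (isotropic; seeded and reproducible). Used
#' to show that centroid-based features are insensitive to the precise organ
#' delineation.
#'
#' @param ref a `reference_point`.
#' @param radius_cm displacement radius, cm (>= 0).
#' @param seed optional integer seed.
#' @return a displaced `reference_point` (organ tag preserved).
#' @export
perturb_reference <- function(ref, radius_cm, seed = NULL) {
  stopifnot(radius_cm >= 0)
  if (radius_cm == 0) return(ref)
  dir <- with_seed(seed, {
    v <- stats::rnorm(3)
    while (sum(v^2) < 1e-12) v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  })
  reference_point(ref$centroid + dir * radius_cm * .units$mm_per_cm,
                  organ = ref$organ)
}

#' Feature vector from analytic lesion geometry
#'
#' Core of the feature extractor, shared by the mask-based path and the
#' synthetic cohort's analytic path: given lesion centroids/volumes and a
#' reference centroid, compute every geometric biomarker. Distances are
#' reported in cm, TMTV in cm^3, the standardized distance in 1/m plus its
#' x100 presentation column.
#'
#' @param lesions a `lesion_set`.
#' @param ref a `reference_point`.
#' @param bsa_m2 body surface area in m^2, or NA when unavailable (the
#'   standardized distance is then NA and the plain distance stands in).
#' @param patient_id id echoed into the row.
#' @param organ_volume_cm3 optional organ volume to carry along.
#' @param invasion optional logical invasion flag to carry along.
#' @return One-row data.frame with columns `patient_id`, `organ`,
#'   `n_lesions`, `tmtv_cm3`, `spread_cm`, `d_ref_cm`, `sd_ref_m1`,
#'   `sd_ref_x100`, `dmax_cm`, `dbulk_cm`, `organ_volume_cm3`, `invasion`,
#'   `bsa_m2`, `mode`.
#' @export
features_from_geometry <- function(lesions, ref, bsa_m2 = NA_real_,
                                   patient_id = NA_character_,
                                   organ_volume_cm3 = NA_real_,
                                   invasion = NA) {
  stopifnot(inherits(lesions, "lesion_set"))
  d_mm <- distances_to_reference(ref, lesions)
  d_ref <- d_reference(d_mm)
  sd_ref <- if (is.finite(bsa_m2) && bsa_m2 > 0)
    standardized_distance(d_ref, bsa_m2) else NA_real_
  data.frame(
    patient_id = patient_id,
    organ = ref$organ,
    n_lesions = nrow(lesions),
    tmtv_cm3 = tmtv(lesions),
    spread_cm = spread(d_mm),
    d_ref_cm = d_ref,
    sd_ref_m1 = sd_ref,
    sd_ref_x100 = 100 * sd_ref,
    dmax_cm = dmax(lesions),
    dbulk_cm = dbulk(lesions),
    organ_volume_cm3 = organ_volume_cm3,
    invasion = invasion,
    bsa_m2 = if (is.finite(bsa_m2)) bsa_m2 else NA_real_,
    mode = attr(lesions, "mode") %||% "analytic",
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the full biomarker vector for one patient
#'
#' Composes the geometric operations: lesion centroids/volumes from the
#' lesion label volume, reference centroid from the (QC-passed) organ mask,
#' then TMTV, SpreadSpleen-style spread, farthest-lesion distance, its
#' body-surface-area standardized form, Dmax, Dbulk, organ volume and the
#' invasion flag. Lesions inside the reference organ are kept in the
#' distance lists. Deterministic: identical inputs give identical outputs.
#'
#' @param patient one-row data.frame (or list) with at least `patient_id`;
#'   `weight_kg`/`height_cm` are used for body surface area when present.
#'   May be NULL (no standardization).
#' @param lesion_vol non-empty lesion [label_volume].
#' @param organ_mask non-empty organ [label_volume] on the same grid.
#' @param organ reference organ tag.
#' @param mode lesion identity mode, see [lesion_centroids].
#' @param connectivity for `connected_components` mode.
#' @return One-row feature data.frame, see [features_from_geometry].
#' @export
extract_features <- function(patient, lesion_vol, organ_mask,
                             organ = "spleen",
                             mode = c("per_label", "connected_components"),
                             connectivity = 26) {
  mode <- match.arg(mode)
  pid <- if (!is.null(patient)) as.character(patient$patient_id) else
    NA_character_
  bsa <- NA_real_
  if (!is.null(patient) &&
      !is.null(patient$weight_kg) && !is.null(patient$height_cm) &&
      isTRUE(is.finite(patient$weight_kg)) &&
      isTRUE(is.finite(patient$height_cm)))
    bsa <- body_surface_area(patient$weight_kg, patient$height_cm)
  lesions <- lesion_centroids(lesion_vol, mode = mode,
                              connectivity = connectivity, patient_id = pid)
  ref <- reference_centroid(organ_mask, organ = organ)
  features_from_geometry(
    lesions, ref, bsa_m2 = bsa, patient_id = pid,
    organ_volume_cm3 = organ_volume(organ_mask),
    invasion = splenic_invasion(lesion_vol, organ_mask)
  )
}
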