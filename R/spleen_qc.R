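#' Connected components of a binary mask
#'
#' Any label > 0 is treated as foreground. Voxel adjacency uses 6- (faces),
#' 18- (faces+edges) or 26-connectivity (faces+edges+corners); 26 is the
#' package default because it is the most permissive and avoids spurious
#' multi-component warnings from thin necks in organ masks. Components are
#' labeled 1, 2, ... in decreasing voxel-count order (ties broken by the
#' smallest linear voxel index) so that label 1 is always the largest
#' component.
#'
#' @param mask a [label_volume].
#' @param connectivity one of 6, 18, 26.
#' @return A list with `labels` (integer array, 0 = background, k = k-th
#'   largest component) and `counts` (voxel count per component, decreasing).
#'   An empty mask yields zero components.
#' @export
connected_components <- function(mask, connectivity = 26) {
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  connectivity <- as.integer(connectivity)
  d <- dim(mask$voxels)
  fg <- which(mask$voxels > 0L)
  labels <- array(0L, dim = d)
  if (length(fg) == 0L)
    return(list(labels = labels, counts = integer(0)))

  coords <- arrayInd(fg, d)            # 1-based
  offs <- neighbor_offsets(connectivity)
  # half-space offsets only: each unordered adjacency appears once
  offs <- offs[offs[, 3] > 0 |
               (offs[, 3] == 0 & (offs[, 2] > 0 |
                                  (offs[, 2] == 0 & offs[, 1] > 0))), ,
               drop = FALSE]
  n <- length(fg)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    ni <- coords[, 1] + offs[r, 1]
    nj <- coords[, 2] + offs[r, 2]
    nk <- coords[, 3] + offs[r, 3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    if (!any(ok)) next
    nlin <- ni[ok] + d[1] * (nj[ok] - 1L) + d[1] * d[2] * (nk[ok] - 1L)
    m <- match(nlin, fg)
    hit <- !is.na(m)
    if (!any(hit)) next
    from <- c(from, which(ok)[hit])
    to <- c(to, m[hit])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  # order: by size descending, then by first (smallest) voxel index
  first_idx <- vapply(seq_along(sizes),
                      function(k) min(fg[memb == k]), numeric(1))
  ord <- order(-sizes, first_idx)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  labels[fg] <- relabel[memb]
  list(labels = labels, counts = sizes[ord])
}

# Neighbor offsets for 6/18/26-connectivity (excluding the origin).
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  deg <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = deg <= 1, "18" = deg <= 2, "26" = deg <= 3)
  unname(g[keep, , drop = FALSE])
}

#' Define the whole-body field-of-view region
#'
#' The region against which spleen containment is tested. Three forms are
#' supported: the full image grid (default, used when no body mask is
#' available), an explicit body mask on the same grid, or an axis-aligned
#' bounding box in 0-based voxel indices.
#'
#' @param vol a [label_volume] defining the grid.
#' @param body_mask optional [label_volume] body outline on the same grid.
#' @param bbox optional list with `lo` and `hi`, 0-based inclusive voxel
#'   index bounds (length-3 each).
#' @return An object of class `fov_region`.
#' @export
body_fov_mask <- function(vol, body_mask = NULL, bbox = NULL) {
  d <- dim(vol$voxels)
  if (!is.null(body_mask)) {
    stop_if_misaligned(vol, body_mask, what = "volume and body mask")
    inside <- body_mask$voxels > 0L
    if (!any(inside)) stop("body mask region is empty")
  } else if (!is.null(bbox)) {
    lo <- pmax(as.integer(bbox$lo), 0L)
    hi <- pmin(as.integer(bbox$hi), d - 1L)
    if (any(hi < lo)) stop("field-of-view bounding box region is empty")
    inside <- array(FALSE, dim = d)
    inside[(lo[1] + 1L):(hi[1] + 1L), (lo[2] + 1L):(hi[2] + 1L),
           (lo[3] + 1L):(hi[3] + 1L)] <- TRUE
  } else {
    inside <- array(TRUE, dim = d)
  }
  structure(list(inside = inside, dim = d), class = "fov_region")
}

# Fraction of a mask's foreground voxels lying inside the FOV region.
fov_containment_fraction <- function(mask, fov) {
  stopifnot(inherits(fov, "fov_region"))
  if (!identical(dim(mask$voxels), fov$dim))
    stop("mask and field-of-view region are on different grids")
  fg <- mask$voxels > 0L
  n <- sum(fg)
  if (n == 0L) return(NA_real_)
  sum(fg & fov$inside) / n
}

#' Quality control of an automatic spleen segmentation
#'
#' Post-processing screen for automatically segmented spleen masks. Two
#' criteria trigger a warning: the mask must be a single connected component,
#' and it must lie inside the whole-body field of view. A multi-component
#' mask is auto-corrected by keeping only the largest component (the spleen
#' proper; satellites are typically segmentation spillover). A mask with less
#' than `fov_threshold` of its voxels inside the field of view, or an empty
#' mask, is flagged for manual review: no geometric correction can help
#' there, so a replacement mask must be supplied by the user.
#'
#' @param mask spleen [label_volume].
#' @param fov optional `fov_region` from [body_fov_mask]; defaults to the
#'   full image grid.
#' @param connectivity voxel connectivity for the component check.
#' @param fov_threshold minimal containment fraction (default 0.95; the
#'   field-of-view check is a sanity screen, not a precise criterion).
#' @param patient_id optional id echoed into the report.
#' @return A list with `mask` (the corrected [label_volume]) and `report`,
#'   a one-row data.frame with columns `patient_id`, `n_components`,
#'   `warning`, `warning_reasons` (comma-joined subset of MULTI_COMPONENT,
#'   OUT_OF_FOV, EMPTY), `auto_corrected`, `spleen_volume_cm3` and
#'   `needs_manual_review`.
#' @export
qc_spleen <- function(mask, fov = NULL, connectivity = 26,
                      fov_threshold = 0.95, patient_id = NA_character_) {
  if (is.null(fov)) fov <- body_fov_mask(mask)
  reasons <- character(0)
  auto_corrected <- FALSE
  needs_review <- FALSE
  corrected <- mask

  n_fg <- sum(mask$voxels > 0L)
  if (n_fg == 0L) {
    reasons <- "EMPTY"
    needs_review <- TRUE
    n_comp <- 0L
  } else {
    cc <- connected_components(mask, connectivity = connectivity)
    n_comp <- length(cc$counts)
    if (n_comp > 1L) {
      reasons <- c(reasons, "MULTI_COMPONENT")
      auto_corrected <- TRUE
      vox <- array(0L, dim = dim(mask$voxels))
      keep <- cc$labels == 1L
      vox[keep] <- mask$voxels[keep]
      corrected <- label_volume(vox, affine = mask$affine,
                                frame_id = mask$frame_id)
    }
    frac <- fov_containment_fraction(corrected, fov)
    if (!is.na(frac) && frac < fov_threshold) {
      reasons <- c(reasons, "OUT_OF_FOV")
      needs_review <- TRUE
    }
  }

  report <- data.frame(
    patient_id = patient_id,
    n_components = n_comp,
    warning = length(reasons) > 0L,
    warning_reasons = paste(reasons, collapse = ";"),
    auto_corrected = auto_corrected,
    spleen_volume_cm3 = organ_volume(corrected),
    needs_manual_review = needs_review,
    stringsAsFactors = FALSE
  )
  list(mask = corrected, report = report)
}

#' Physical volume of a mask
#'
#' Foreground voxel count times the physical voxel volume, in cm^3. Used for
#' the spleen volume in QC reports and for lesion volumes.
#'
#' @param mask a [label_volume].
#' @return volume in cm^3.
#' @export
organ_volume <- function(mask) {
  mm3_to_cm3(sum(mask$voxels > 0L) * voxel_volume_mm3(mask))
}
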