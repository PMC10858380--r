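#' 3D label volumes with physical coordinates
#'
#' A `label_volume` is the common carrier for lesion and organ masks: a 3D
#' array of non-negative integer labels (0 = background) together with a 4x4
#' affine mapping 0-based voxel indices to physical coordinates in
#' millimeters (the NIfTI convention). Voxel spacing is derived from the
#' affine column norms. All downstream geometry (centroids, distances,
#' volumes) is computed in physical millimeters through this affine, using
#' the voxel-center convention: the centroid of voxel (i, j, k) is
#' `affine %*% c(i, j, k, 1)`.
#'
#' @param voxels 3D array of non-negative integers (values within 1e-6 of an
#'   integer are rounded; anything else is rejected).
#' @param affine 4x4 invertible matrix, voxel-index -> mm.
#' @param frame_id character tag naming the acquisition grid; volumes must
#'   share a grid (same shape and affine) to be combined.
#' @return An object of class `label_volume` with elements `voxels`,
#'   `affine`, `spacing` (mm/voxel along each axis) and `frame_id`.
#' @examples
#' vox <- array(0L, dim = c(8, 8, 8))
#' vox[3, 4, 5] <- 1L
#' vol <- label_volume(vox, affine = diag(c(2, 2, 3, 1)))
#' vol$spacing
#' @export
label_volume <- function(voxels, affine = diag(4), frame_id = "frame-1") {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array, got ", length(dim(voxels)), " dimensions")
  voxels <- coerce_integer_labels(voxels)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps * 64)
    stop("`affine` is not invertible")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0))
    stop("voxel spacing must be strictly positive")
  structure(
    list(voxels = voxels, affine = affine, spacing = spacing,
         frame_id = as.character(frame_id)),
    class = "label_volume"
  )
}

# Round near-integer values, reject genuinely non-integer data, reject
# negatives. Tolerance 1e-6 absorbs float storage of integer labels.
coerce_integer_labels <- function(voxels, tol = 1e-6) {
  if (is.integer(voxels)) {
    if (any(voxels < 0L, na.rm = TRUE)) stop("labels must be >= 0")
    if (anyNA(voxels)) stop("labels must not contain NA")
    return(array(as.integer(voxels), dim = dim(voxels)))
  }
  v <- as.numeric(voxels)
  if (anyNA(v)) stop("labels must not contain NA")
  r <- round(v)
  if (any(abs(v - r) > tol))
    stop("voxel data is not integer-valued (max deviation ",
         format(max(abs(v - r))), ")")
  if (any(r < 0)) stop("labels must be >= 0")
  out <- array(as.integer(r), dim = dim(voxels))
  out
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  labs <- sort(unique(x$voxels[x$voxels > 0L]))
  cat(sprintf("<label_volume> %dx%dx%d, spacing %s mm, frame '%s'\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = "x"),
              x$frame_id))
  cat(sprintf("  foreground voxels: %d (%d label%s)\n",
              sum(x$voxels > 0L), length(labs),
              if (length(labs) == 1L) "" else "s"))
  invisible(x)
}

#' Map 0-based voxel indices to physical mm
#' @param vol a `label_volume`.
#' @param ijk numeric matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of physical coordinates (mm).
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk, 1)
  out <- h %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

#' Map physical mm to (fractional) 0-based voxel indices
#' @inheritParams voxel_to_world
#' @param xyz numeric matrix (n x 3) of physical coordinates (mm).
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(vol$affine))
  out[, 1:3, drop = FALSE]
}

# Physical mm^3 of one voxel (parallelepiped spanned by the affine columns).
voxel_volume_mm3 <- function(vol) abs(det(vol$affine[1:3, 1:3]))

# 0-based voxel indices (n x 3) of foreground voxels, optionally of one label.
foreground_indices <- function(vol, label = NULL) {
  sel <- if (is.null(label)) vol$voxels > 0L else vol$voxels == label
  idx <- which(sel)
  arrayInd(idx, dim(vol$voxels)) - 1L
}

#' Read a NIfTI label volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [label_volume], taking the affine
#' from the NIfTI xform (sform/qform). Non-integer voxel values within 1e-6
#' of an integer are rounded; other values are rejected.
#'
#' @param path path to a NIfTI file.
#' @param frame_id optional grid tag; defaults to the file name.
#' @return a [label_volume].
#' @export
read_label_volume <- function(path, frame_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected 3D data in ", path, ", got ", length(dim(arr)), "D")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  if (is.null(frame_id)) frame_id <- basename(path)
  label_volume(arr, affine = affine, frame_id = frame_id)
}

#' Write a label volume to NIfTI
#' @param vol a [label_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two volumes share an acquisition grid
#'
#' Lesion and organ masks must be co-registered before any spatial
#' comparison. Two volumes are considered aligned when their array shapes
#' match and their affines agree elementwise within `tol` millimeters.
#' This is a verdict, not an exception: misalignment is reported with the
#' maximal affine deviation so the caller can decide to resample.
#'
#' @param a,b [label_volume] objects.
#' @param tol tolerance in mm for affine agreement (default 1e-3).
#' @return A list with `aligned` (logical), `max_deviation` (mm; NA when
#'   shapes differ), and `reason` (`"ALIGNED"`, `"SHAPE_MISMATCH"` or
#'   `"AFFINE_MISMATCH"`).
#' @export
check_grid_alignment <- function(a, b, tol = 1e-3) {
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    return(list(aligned = FALSE, max_deviation = NA_real_,
                reason = "SHAPE_MISMATCH"))
  }
  dev <- max(abs(a$affine - b$affine))
  if (dev > tol) {
    return(list(aligned = FALSE, max_deviation = dev,
                reason = "AFFINE_MISMATCH"))
  }
  list(aligned = TRUE, max_deviation = dev, reason = "ALIGNED")
}

stop_if_misaligned <- function(a, b, what = "volumes", tol = 1e-3) {
  v <- check_grid_alignment(a, b, tol = tol)
  if (!v$aligned)
    stop(what, " are on different grids (", v$reason,
         if (is.finite(v$max_deviation))
           sprintf(", max affine deviation %.4g mm", v$max_deviation) else "",
         "); resample explicitly with resample_labels_nearest()")
  invisible(v)
}

#' Resample a label volume onto another grid (nearest neighbor)
#'
#' Recovery path for masks delivered on mismatched grids. Each target voxel
#' center is mapped to physical space and assigned the label of the nearest
#' source voxel; labels are never interpolated, so the output label set is a
#' subset of the input label set. Resampling moves centroids by up to one
#' voxel, which is why grid mismatch is a hard error elsewhere and this step
#' is always explicit.
#'
#' @param vol source [label_volume].
#' @param target [label_volume] whose grid defines the output.
#' @return a [label_volume] on `target`'s grid.
#' @export
resample_labels_nearest <- function(vol, target) {
  ds <- dim(vol$voxels); dt <- dim(target$voxels)
  if (sum(vol$voxels > 0L) > 0L && !extents_overlap(vol, target))
    stop("physical extents of the two grids do not overlap")
  tgt_ijk <- as.matrix(expand.grid(i = 0:(dt[1] - 1L), j = 0:(dt[2] - 1L),
                                   k = 0:(dt[3] - 1L)))
  world <- voxel_to_world(target, tgt_ijk)
  src <- round(world_to_voxel(vol, world))
  ok <- src[, 1] >= 0 & src[, 1] < ds[1] &
        src[, 2] >= 0 & src[, 2] < ds[2] &
        src[, 3] >= 0 & src[, 3] < ds[3]
  out <- integer(prod(dt))
  lin <- src[ok, 1] + ds[1] * (src[ok, 2] + ds[2] * src[ok, 3]) + 1
  out[ok] <- vol$voxels[lin]
  label_volume(array(out, dim = dt), affine = target$affine,
               frame_id = target$frame_id)
}

# Axis-aligned physical bounding boxes (of the full grids) intersect?
extents_overlap <- function(a, b) {
  box <- function(v) {
    d <- dim(v$voxels)
    corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                     c(0, d[3] - 1)))
    w <- voxel_to_world(v, corners)
    rbind(apply(w, 2, min), apply(w, 2, max))
  }
  ba <- box(a); bb <- box(b)
  all(ba[1, ] <= bb[2, ] & bb[1, ] <= ba[2, ])
}
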