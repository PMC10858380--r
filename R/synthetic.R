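#' Specify a single-patient phantom
#'
#' A phantom is a pair of co-registered label volumes: an ellipsoidal spleen
#' (label 1, optionally with small satellite blobs to exercise the QC path)
#' and a set of spherical lesions with distinct labels. Spheres are used for
#' lesions because only centroids and volumes matter downstream; the spleen
#' is an ellipsoid so its centroid is distinct from any bounding-box center.
#' All shapes are digitized by the voxel-center inclusion test, so a spec
#' maps deterministically to voxel data.
#'
#' @param grid_shape integer length-3 array dimensions.
#' @param spacing voxel spacing, mm (length 3).
#' @param spleen list with `center` (mm, length 3) and `radii` (mm, length
#'   3, ellipsoid semi-axes).
#' @param lesions data.frame with columns `cx`, `cy`, `cz` (mm),
#'   `radius_mm`, `label` (distinct integers > 0).
#' @param satellites optional data.frame with `cx`, `cy`, `cz`, `radius_mm`:
#'   extra blobs added to the spleen mask (same label) to trigger
#'   multi-component QC warnings.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), spacing = c(4, 4, 4),
                         spleen = list(center = c(192, 192, 192),
                                       radii = c(30, 40, 50)),
                         lesions = data.frame(cx = 100, cy = 100, cz = 100,
                                              radius_mm = 15, label = 1L),
                         satellites = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            length(spacing) == 3L, all(spacing > 0))
  if (anyDuplicated(lesions$label) || any(lesions$label <= 0))
    stop("lesion labels must be distinct integers > 0")
  extent <- (grid_shape - 0.5) * spacing
  inside <- function(center, radii) {
    all(center - radii >= -0.5 * spacing) && all(center + radii <= extent)
  }
  if (!inside(spleen$center, spleen$radii))
    stop("spleen does not fit inside the grid")
  for (i in seq_len(nrow(lesions)))
    if (!inside(c(lesions$cx[i], lesions$cy[i], lesions$cz[i]),
                rep(lesions$radius_mm[i], 3)))
      stop("lesion ", lesions$label[i], " does not fit inside the grid")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 spleen = spleen, lesions = lesions,
                 satellites = satellites),
            class = "phantom_spec")
}

# Digitize one ellipsoid into an existing voxel array (voxel-center
# inclusion; assign `label`, later calls overwrite earlier ones).
fill_ellipsoid <- function(vox, spacing, center, radii, label) {
  d <- dim(vox)
  lo <- pmax(floor((center - radii) / spacing), 0)
  hi <- pmin(ceiling((center + radii) / spacing), d - 1L)
  if (any(hi < lo)) return(list(vox = vox, n_overlap = 0L))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- expand.grid(i = ii, j = jj, k = kk)
  x <- (g$i * spacing[1] - center[1]) / radii[1]
  y <- (g$j * spacing[2] - center[2]) / radii[2]
  z <- (g$k * spacing[3] - center[3]) / radii[3]
  sel <- x^2 + y^2 + z^2 <= 1
  lin <- g$i[sel] + d[1] * (g$j[sel] + d[2] * g$k[sel]) + 1
  n_overlap <- sum(vox[lin] > 0L)
  vox[lin] <- as.integer(label)
  list(vox = vox, n_overlap = n_overlap)
}

#' Build phantom label volumes from a spec
#'
#' Deterministic digitization of the spec's shapes onto the grid (affine =
#' diagonal spacing, origin at voxel (0,0,0)). When two lesion spheres claim
#' the same voxel the higher label wins; the number of reassigned voxels is
#' recorded in the `n_overlap` attribute of the lesion volume.
#'
#' @param spec a [phantom_spec].
#' @return list with `lesions` and `spleen`, both [label_volume]s on the
#'   same grid.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  affine <- diag(c(spec$spacing, 1))
  frame <- "phantom-grid"

  svox <- array(0L, dim = d)
  svox <- fill_ellipsoid(svox, spec$spacing, spec$spleen$center,
                         spec$spleen$radii, 1L)$vox
  if (!is.null(spec$satellites)) {
    for (i in seq_len(nrow(spec$satellites))) {
      s <- spec$satellites[i, ]
      svox <- fill_ellipsoid(svox, spec$spacing, c(s$cx, s$cy, s$cz),
                             rep(s$radius_mm, 3), 1L)$vox
    }
  }

  lvox <- array(0L, dim = d)
  n_overlap <- 0L
  les <- spec$lesions[order(spec$lesions$label), , drop = FALSE]
  for (i in seq_len(nrow(les))) {
    r <- fill_ellipsoid(lvox, spec$spacing,
                        c(les$cx[i], les$cy[i], les$cz[i]),
                        rep(les$radius_mm[i], 3), les$label[i])
    lvox <- r$vox
    n_overlap <- n_overlap + r$n_overlap
  }
  lesions <- label_volume(lvox, affine = affine, frame_id = frame)
  attr(lesions, "n_overlap") <- n_overlap
  list(lesions = lesions,
       spleen = label_volume(svox, affine = affine, frame_id = frame))
}

#' Specify a synthetic patient cohort
#'
#' Emulates the study conditions the package is designed for: one phantom
#' per patient (ellipsoidal spleen at a fixed left-upper-quadrant offset of
#' a body ellipsoid, 1 + Poisson(lambda) spherical lesions placed uniformly
#' in the body, log-normal lesion radii), clinical covariates, and
#' proportional-hazards survival. Progression times follow a Weibull
#' baseline hazard multiplied by exp of a linear predictor over the
#' standardized true features; death times add an exponential
#' post-progression survival so PFS never exceeds OS; independent
#' exponential censoring plus an administrative follow-up horizon. The
#' defaults give roughly a 26% observed event share by 48 months and leave
#' lesion positions independent of lesion volumes, so distance features
#' decorrelate from TMTV.
#'
#' @param n_patients cohort size.
#' @param grid_shape,spacing phantom grid (default 96^3 voxels at 4 mm).
#' @param body_semiaxes body ellipsoid semi-axes, mm; the defaults keep any
#'   lesion sphere inside the default grid, so cohorts are always
#'   renderable.
#' @param spleen_offset spleen center offset from the body center, mm.
#' @param spleen_radii nominal spleen semi-axes, mm (jittered 0.85-1.15x
#'   per patient; nominal volume ~251 cm^3).
#' @param lesion_lambda lesion count is 1 + Poisson(lambda).
#' @param lesion_radius_meanlog,lesion_radius_sdlog log-normal lesion radius
#'   law, mm; clamped to `lesion_radius_range`.
#' @param lesion_radius_range allowed radius range, mm.
#' @param weight_mean,weight_sd,height_mean,height_sd clinical covariate
#'   laws (normal, truncated positive).
#' @param ipi_probs sampling probabilities for age-adjusted IPI 1/2/3.
#' @param betas named log-hazard-ratio coefficients per standardized
#'   feature; names among `tmtv`, `spread`, `d_ref`, `sd_ref_x100`, `dmax`,
#'   `dbulk`, `ipi`, `invasion`.
#' @param weibull_shape,weibull_scale baseline Weibull hazard (scale in
#'   months).
#' @param censor_rate independent exponential censoring rate (1/months).
#' @param admin_horizon administrative censoring, months.
#' @param post_progression_mean mean months from progression to death.
#' @param seed integer seed; mandatory for reproducible cohorts.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 300,
                        grid_shape = c(96, 96, 96), spacing = c(4, 4, 4),
                        body_semiaxes = c(145, 105, 145),
                        spleen_offset = c(85, -35, 70),
                        spleen_radii = c(30, 40, 50),
                        lesion_lambda = 4,
                        lesion_radius_meanlog = log(17),
                        lesion_radius_sdlog = 0.5,
                        lesion_radius_range = c(6, 40),
                        weight_mean = 73, weight_sd = 12,
                        height_mean = 168, height_sd = 10,
                        ipi_probs = c(0.35, 0.45, 0.20),
                        betas = c(tmtv = 0.4, d_ref = 0.7, ipi = 0.25),
                        weibull_shape = 1.2, weibull_scale = 140,
                        censor_rate = 1 / 240, admin_horizon = 84,
                        post_progression_mean = 30,
                        seed = 1L) {
  spec <- as.list(environment())
  stopifnot(n_patients >= 1, lesion_lambda >= 0, censor_rate >= 0,
            weibull_shape > 0, weibull_scale > 0,
            all(is.finite(betas)))
  known <- c("tmtv", "spread", "d_ref", "sd_ref_x100", "dmax", "dbulk",
             "ipi", "invasion")
  if (length(betas) && (is.null(names(betas)) ||
                        !all(names(betas) %in% known)))
    stop("betas must be named among: ", paste(known, collapse = ", "))
  structure(spec, class = "cohort_spec")
}

# Draw one patient's geometry (analytic, mm). Lesion positions are uniform
# in the body ellipsoid and independent of radii by construction.
draw_patient_geometry <- function(spec) {
  center <- (spec$grid_shape - 1) * spec$spacing / 2
  spleen_center <- center + spec$spleen_offset
  spleen_radii <- spec$spleen_radii * stats::runif(3, 0.85, 1.15)
  n_lesions <- 1L + stats::rpois(1, spec$lesion_lambda)
  pos <- matrix(NA_real_, 0, 3)
  while (nrow(pos) < n_lesions) {
    m <- 2L * (n_lesions - nrow(pos)) + 4L
    u <- matrix(stats::runif(3L * m, -1, 1), ncol = 3)
    u <- u[rowSums(u^2) <= 1, , drop = FALSE]
    pos <- rbind(pos, u)
  }
  pos <- pos[seq_len(n_lesions), , drop = FALSE]
  pos <- sweep(pos, 2, spec$body_semiaxes, `*`)
  pos <- sweep(pos, 2, center, `+`)
  radii <- stats::rlnorm(n_lesions, spec$lesion_radius_meanlog,
                         spec$lesion_radius_sdlog)
  radii <- pmin(pmax(radii, spec$lesion_radius_range[1]),
                spec$lesion_radius_range[2])
  list(spleen_center = spleen_center, spleen_radii = spleen_radii,
       xyz = pos, radii = radii)
}

# Approximate analytic invasion flag: a lesion sphere intersects the spleen
# ellipsoid if its center lies within the ellipsoid dilated by the lesion
# radius (exact for spheres, a close bound for mild ellipsoid anisotropy).
analytic_invasion <- function(geom) {
  u <- sweep(geom$xyz, 2, geom$spleen_center)
  any(rowSums((u / outer(geom$radii, geom$spleen_radii, `+`))^2) <= 1)
}

#' Simulate a synthetic cohort with known ground truth
#'
#' For each patient: draw geometry, compute the true (analytic) feature
#' vector, then draw survival by inverting the Weibull cumulative hazard
#' scaled by exp of the linear predictor (closed form, no root finding).
#' With `render = TRUE` phantom label volumes are also built and features
#' re-extracted through the full image pipeline; the analytic path is the
#' default so large Monte-Carlo studies stay tractable, and the equivalence
#' of the two paths (up to voxelization error) is part of the test suite.
#'
#' @param spec a [cohort_spec].
#' @param render build voxel phantoms and extract features from them?
#' @return a `cohort_sim` list: `clinical` (CSV-shaped data.frame), `truth`
#'   (true features, linear predictor, latent times), `features` (extracted
#'   features: analytic, or image-derived when rendered), `phantoms` (list
#'   of phantom pairs, or NULL), `spec`.
#' @export
simulate_cohort <- function(spec, render = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    ids <- sprintf("P%03d", seq_len(n))

    geoms <- lapply(seq_len(n), function(i) draw_patient_geometry(spec))
    weight <- pmax(40, stats::rnorm(n, spec$weight_mean, spec$weight_sd))
    height <- pmax(140, stats::rnorm(n, spec$height_mean, spec$height_sd))
    ipi <- sample(1:3, n, replace = TRUE, prob = spec$ipi_probs)
    bsa <- body_surface_area(weight, height)

    # analytic feature math shared with features_from_geometry, assembled
    # without per-patient data.frame overhead (cohort loops are hot)
    nles <- spr <- dref <- dmx <- dbk <- tv <- ov <- numeric(n)
    inv <- logical(n)
    for (i in seq_len(n)) {
      g <- geoms[[i]]
      xyz <- g$xyz
      vols <- mm3_to_cm3(4 / 3 * pi * g$radii^3)
      d <- sqrt((xyz[, 1] - g$spleen_center[1])^2 +
                (xyz[, 2] - g$spleen_center[2])^2 +
                (xyz[, 3] - g$spleen_center[3])^2)
      nles[i] <- nrow(xyz)
      spr[i] <- spread(d)
      dref[i] <- d_reference(d)
      dmx[i] <- dmax_points(xyz)
      dbk[i] <- dbulk_points(xyz, vols)
      tv[i] <- sum(vols)
      ov[i] <- mm3_to_cm3(4 / 3 * pi * prod(g$spleen_radii))
      inv[i] <- analytic_invasion(g)
    }
    sd_ref <- standardized_distance(dref, bsa)
    truth <- data.frame(
      patient_id = ids, organ = "spleen", n_lesions = as.integer(nles),
      tmtv_cm3 = tv, spread_cm = spr, d_ref_cm = dref, sd_ref_m1 = sd_ref,
      sd_ref_x100 = 100 * sd_ref, dmax_cm = dmx, dbulk_cm = dbk,
      organ_volume_cm3 = ov, invasion = inv, bsa_m2 = bsa,
      mode = "analytic", ipi = ipi, stringsAsFactors = FALSE)

    # linear predictor over standardized true features
    cols <- c(tmtv = "tmtv_cm3", spread = "spread_cm", d_ref = "d_ref_cm",
              sd_ref_x100 = "sd_ref_x100", dmax = "dmax_cm",
              dbulk = "dbulk_cm", ipi = "ipi", invasion = "invasion")
    lp <- rep(0, n)
    for (nm in names(spec$betas)) {
      x <- as.numeric(truth[[cols[[nm]]]])
      s <- stats::sd(x)
      z <- if (s > 0) (x - mean(x)) / s else rep(0, n)
      lp <- lp + spec$betas[[nm]] * z
    }
    truth$lp <- lp

    u <- stats::runif(n)
    t_prog <- spec$weibull_scale * (-log(u) * exp(-lp))^(1 / spec$weibull_shape)
    t_death <- t_prog + stats::rexp(n, 1 / spec$post_progression_mean)
    cens <- if (spec$censor_rate > 0) stats::rexp(n, spec$censor_rate)
            else rep(Inf, n)
    cens <- pmin(cens, spec$admin_horizon)
    truth$t_progression <- t_prog
    truth$t_death <- t_death
    truth$t_censor <- cens

    clinical <- data.frame(
      patient_id = ids,
      weight_kg = round(weight, 1),
      height_cm = round(height, 1),
      ipi = ipi,
      pfs_months = round(pmin(t_prog, cens), 4),
      pfs_event = as.integer(t_prog <= cens),
      os_months = round(pmin(t_death, cens), 4),
      os_event = as.integer(t_death <= cens),
      stringsAsFactors = FALSE
    )

    phantoms <- NULL
    features <- truth[, c("patient_id", "organ", "n_lesions", "tmtv_cm3",
                          "spread_cm", "d_ref_cm", "sd_ref_m1",
                          "sd_ref_x100", "dmax_cm", "dbulk_cm",
                          "organ_volume_cm3", "invasion", "bsa_m2", "mode")]
    if (render) {
      phantoms <- vector("list", n)
      features <- vector("list", n)
      for (i in seq_len(n)) {
        g <- geoms[[i]]
        ps <- phantom_spec(grid_shape = spec$grid_shape,
                           spacing = spec$spacing,
                           spleen = list(center = g$spleen_center,
                                         radii = g$spleen_radii),
                           lesions = data.frame(
                             cx = g$xyz[, 1], cy = g$xyz[, 2],
                             cz = g$xyz[, 3], radius_mm = g$radii,
                             label = seq_along(g$radii)))
        ph <- make_phantom(ps)
        phantoms[[i]] <- ph
        features[[i]] <- extract_features(
          list(patient_id = ids[i], weight_kg = weight[i],
               height_cm = height[i]),
          ph$lesions, ph$spleen, organ = "spleen", mode = "per_label")
      }
      features <- do.call(rbind, features)
      names(phantoms) <- ids
    }
    rownames(truth) <- rownames(features) <- NULL

    structure(list(clinical = clinical, truth = truth, features = features,
                   phantoms = phantoms, geoms = geoms, spec = spec),
              class = "cohort_sim")
  })
}

#' Check decorrelation of dissemination features from tumor burden
#'
#' The generator draws lesion positions independently of lesion volumes, so
#' the spleen-referenced distance features should be (nearly) uncorrelated
#' with TMTV. This helper reports the achieved Pearson correlations on a
#' simulated cohort's ground truth.
#'
#' @param truth the `truth` table of a [simulate_cohort] result (or any
#'   data.frame with the feature columns).
#' @param features columns to correlate against `against`.
#' @param against burden column (default `tmtv_cm3`).
#' @return data.frame with `feature` and achieved `rho`.
#' @export
decorrelate_check <- function(truth,
                              features = c("spread_cm", "d_ref_cm",
                                           "sd_ref_x100"),
                              against = "tmtv_cm3") {
  rho <- vapply(features, function(f)
    stats::cor(truth[[f]], truth[[against]], use = "complete.obs"),
    numeric(1))
  data.frame(feature = features, against = against, rho = unname(rho),
             stringsAsFactors = FALSE)
}
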