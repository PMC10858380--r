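two_lesion_set <- function() {
  lesion_set(data.frame(lesion_id = 1:2, cx = c(30, 0), cy = c(0, 40),
                        cz = c(0, 0), volume_cm3 = c(10, 2)))
}

test_that("lesion centroids match hand-computed voxel means", {
  vox <- array(0L, dim = c(16, 16, 16))
  # L-shaped lesion: voxels (2,2,2),(3,2,2),(4,2,2),(4,3,2) 0-based
  vox[3, 3, 3] <- 1L; vox[4, 3, 3] <- 1L; vox[5, 3, 3] <- 1L
  vox[5, 4, 3] <- 1L
  vol <- label_volume(vox, affine = diag(c(2, 2, 2, 1)))
  ls <- lesion_centroids(vol)
  pts <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2), c(4, 3, 2)) * 2
  expect_equal(c(ls$cx, ls$cy, ls$cz), colMeans(pts), tolerance = 1e-12)
  expect_equal(ls$volume_cm3, 4 * 8 / 1000)

  # two labels, symmetric cubes
  vox2 <- array(0L, dim = c(32, 32, 32))
  vox2[10:12, 5:7, 5:7] <- 1L
  vox2[4:6, 15:17, 5:7] <- 2L
  vol2 <- label_volume(vox2)
  ls2 <- lesion_centroids(vol2)
  expect_equal(ls2$lesion_id, 1:2)
  expect_equal(c(ls2$cx[1], ls2$cy[1], ls2$cz[1]), c(10, 5, 5))
  expect_equal(c(ls2$cx[2], ls2$cy[2], ls2$cz[2]), c(4, 15, 5))
  expect_error(lesion_centroids(label_volume(array(0L, dim = c(4, 4, 4)))),
               "empty")
})

test_that("connected-components mode splits unlabeled foreground", {
  vox <- array(0L, dim = c(24, 24, 24))
  vox[2:4, 2:4, 2:4] <- 7L
  vox[12:14, 12:14, 12:14] <- 7L
  vol <- label_volume(vox)
  expect_equal(nrow(lesion_centroids(vol, mode = "per_label")), 1L)
  ls <- lesion_centroids(vol, mode = "connected_components")
  expect_equal(nrow(ls), 2L)
  expect_identical(attr(ls, "mode"), "connected_components")
})

test_that("reference centroid recovers analytic centers", {
  spec <- phantom_spec(grid_shape = c(64, 64, 64), spacing = c(2, 2, 2),
                       spleen = list(center = c(60, 50, 80),
                                     radii = c(18, 18, 18)),
                       lesions = data.frame(cx = 10, cy = 10, cz = 10,
                                            radius_mm = 4, label = 1L))
  ph <- make_phantom(spec)
  ref <- reference_centroid(ph$spleen)
  expect_lt(max(abs(ref$centroid - c(60, 50, 80))), 1)  # half a 2mm voxel

  vox <- array(0L, dim = c(16, 16, 16))
  vox[1, 1, 1] <- 1L; vox[11, 1, 1] <- 1L
  midpoint <- reference_centroid(label_volume(vox))
  expect_equal(midpoint$centroid, c(5, 0, 0))
  expect_error(reference_centroid(label_volume(array(0L, c(2, 2, 2)))),
               "empty")
})

test_that("distances, spread, d_reference agree with hand arithmetic", {
  ls <- two_lesion_set()
  ref <- reference_point(c(0, 0, 0))
  d <- distances_to_reference(ref, ls)
  expect_equal(d, c(30, 40))
  expect_equal(spread(d), 0.5)          # mu=35, sigma=5mm
  expect_equal(d_reference(d), 4.0)
  expect_equal(spread(123), 0)          # single lesion
  expect_equal(spread(c(7, 7, 7)), 0)   # all equal

  # translation invariance
  shift <- c(5, -7, 12)
  ls2 <- ls; ls2$cx <- ls2$cx + shift[1]; ls2$cy <- ls2$cy + shift[2]
  ls2$cz <- ls2$cz + shift[3]
  d2 <- distances_to_reference(reference_point(shift), ls2)
  expect_equal(d2, d, tolerance = 1e-12)
})

test_that("body surface area and standardized distance match arithmetic", {
  expect_equal(body_surface_area(72, 168), sqrt(12096) / 60,
               tolerance = 1e-12)
  expect_equal(body_surface_area(36, 100), 1.0)
  expect_error(body_surface_area(0, 168), "positive")
  expect_error(body_surface_area(72, -1), "positive")

  bsa <- body_surface_area(72, 168)
  expect_equal(100 * standardized_distance(32.43, bsa), 17.6920,
               tolerance = 1e-3)
  expect_equal(standardized_distance(0, 1.5), 0)
  expect_equal(standardized_distance(20, 2), standardized_distance(20, 1) / 2)
  expect_error(standardized_distance(10, NA_real_), "positive")
})

test_that("dmax and dbulk follow the 3-4-5 construction and tie rules", {
  ls <- two_lesion_set()
  expect_equal(dmax(ls), 5.0)
  expect_equal(dbulk(ls), 5.0)  # bulk = lesion 1 (10 cm^3)
  single <- lesion_set(data.frame(lesion_id = 1L, cx = 1, cy = 2, cz = 3,
                                  volume_cm3 = 5))
  expect_equal(dmax(single), 0)
  expect_equal(dbulk(single), 0)

  # volume tie -> lowest lesion_id is the bulk
  tie <- lesion_set(data.frame(lesion_id = 1:3, cx = c(0, 10, 100),
                               cy = 0, cz = 0, volume_cm3 = c(5, 5, 1)))
  expect_equal(dbulk(tie), 10.0)  # from lesion 1, not lesion 2 (9.0)
})

test_that("geometric features equal the brute-force oracle on random configs", {
  set.seed(7)
  for (i in 1:200) {
    cfg <- random_lesion_config()
    ls <- lesion_set_from_config(cfg)
    ref <- reference_point(cfg$ref)
    d <- distances_to_reference(ref, ls)
    want <- oracle_features(cfg$centroids, cfg$volumes, cfg$ref)
    expect_equal(spread(d), want$spread, tolerance = 1e-12)
    expect_equal(d_reference(d), want$d_ref, tolerance = 1e-12)
    expect_equal(dmax(ls), want$dmax, tolerance = 1e-12)
    expect_equal(dbulk(ls), want$dbulk, tolerance = 1e-12)
    expect_equal(tmtv(ls), want$tmtv, tolerance = 1e-12)
    expect_gte(dmax(ls), dbulk(ls))
  }
})

test_that("tmtv sums volumes and is order-invariant", {
  ls <- lesion_set(data.frame(lesion_id = 1:3, cx = 1:3, cy = 1, cz = 1,
                              volume_cm3 = c(10, 2, 0.5)))
  expect_equal(tmtv(ls), 12.5)
  perm <- lesion_set(ls[c(3, 1, 2), ])  # re-sorts by id internally
  expect_equal(tmtv(perm), 12.5)
})

test_that("splenic invasion detects voxel overlap, not adjacency", {
  d <- c(16, 16, 16)
  les <- array(0L, dim = d); spl <- array(0L, dim = d)
  les[2:4, 2:4, 2:4] <- 1L
  spl[10:12, 10:12, 10:12] <- 1L
  mk <- function(v) label_volume(v)
  expect_false(splenic_invasion(mk(les), mk(spl)))

  spl2 <- spl; spl2[4, 4, 4] <- 1L  # one shared voxel
  expect_true(splenic_invasion(mk(les), mk(spl2)))

  spl3 <- array(0L, dim = d); spl3[5:7, 2:4, 2:4] <- 1L  # face-adjacent
  expect_false(splenic_invasion(mk(les), mk(spl3)))

  other_grid <- label_volume(spl, affine = diag(c(2, 2, 2, 1)))
  expect_error(splenic_invasion(mk(les), other_grid), "different grids")
})

test_that("reference perturbation has exact radius and is seeded", {
  ref <- reference_point(c(100, 50, 80))
  expect_identical(perturb_reference(ref, 0), ref)
  for (s in 1:20) {
    p <- perturb_reference(ref, 2, seed = s)
    expect_equal(sqrt(sum((p$centroid - ref$centroid)^2)), 20,
                 tolerance = 1e-9)
  }
  expect_equal(perturb_reference(ref, 2, seed = 3)$centroid,
               perturb_reference(ref, 2, seed = 3)$centroid)

  # triangle inequality: d_ref moves by at most the perturbation radius
  ls <- two_lesion_set()
  d0 <- d_reference(distances_to_reference(ref, ls))
  for (s in 1:25) {
    p <- perturb_reference(ref, 2, seed = s)
    d1 <- d_reference(distances_to_reference(p, ls))
    expect_lte(abs(d1 - d0), 2 + 1e-9)
  }
})

test_that("rigid motions leave all distance features unchanged", {
  set.seed(11)
  for (i in 1:25) {
    cfg <- random_lesion_config()
    ls <- lesion_set_from_config(cfg)
    ref <- reference_point(cfg$ref)
    d0 <- distances_to_reference(ref, ls)
    base <- c(spread(d0), d_reference(d0), dmax(ls), dbulk(ls))

    R <- random_rotation(); tr <- runif(3, -50, 50)
    xyz <- as.matrix(ls[, c("cx", "cy", "cz")]) %*% t(R)
    xyz <- sweep(xyz, 2, tr, `+`)
    ls2 <- lesion_set(data.frame(lesion_id = ls$lesion_id, cx = xyz[, 1],
                                 cy = xyz[, 2], cz = xyz[, 3],
                                 volume_cm3 = ls$volume_cm3))
    ref2 <- reference_point(as.vector(R %*% cfg$ref) + tr)
    d1 <- distances_to_reference(ref2, ls2)
    moved <- c(spread(d1), d_reference(d1), dmax(ls2), dbulk(ls2))
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("scaling coordinates by k scales distances by k and TMTV by k^3", {
  cfg <- random_lesion_config()
  ls <- lesion_set_from_config(cfg)
  ref <- reference_point(cfg$ref)
  d0 <- distances_to_reference(ref, ls)
  k <- 2.5
  ls2 <- lesion_set(data.frame(lesion_id = ls$lesion_id, cx = k * ls$cx,
                               cy = k * ls$cy, cz = k * ls$cz,
                               volume_cm3 = k^3 * ls$volume_cm3))
  d1 <- distances_to_reference(reference_point(k * cfg$ref), ls2)
  expect_equal(spread(d1), k * spread(d0), tolerance = 1e-9)
  expect_equal(dmax(ls2), k * dmax(ls), tolerance = 1e-9)
  expect_equal(tmtv(ls2), k^3 * tmtv(ls), tolerance = 1e-9)
})

test_that("extract_features composes the hand-checked case end to end", {
  # analytic construction digitized at 1 mm: lesions centered at voxel
  # centers so centroids are near-exact
  spec <- phantom_spec(
    grid_shape = c(96, 96, 64), spacing = c(1, 1, 1),
    spleen = list(center = c(30, 30, 30), radii = c(8, 10, 12)),
    lesions = data.frame(cx = c(70, 20), cy = c(20, 80), cz = c(30, 30),
                         radius_mm = c(6, 5), label = 1:2))
  ph <- make_phantom(spec)
  fv <- extract_features(list(patient_id = "P1", weight_kg = 72,
                              height_cm = 168),
                         ph$lesions, ph$spleen)
  expect_equal(fv$n_lesions, 2L)
  expect_equal(fv$dmax_cm, sqrt(50^2 + 60^2) / 10, tolerance = 0.02)
  expect_false(fv$invasion)
  expect_equal(fv$bsa_m2, body_surface_area(72, 168))
  expect_identical(fv$organ, "spleen")
  # deterministic
  fv2 <- extract_features(list(patient_id = "P1", weight_kg = 72,
                               height_cm = 168),
                          ph$lesions, ph$spleen)
  expect_identical(fv, fv2)

  # liver parameterization reuses the same pipeline
  fl <- extract_features(NULL, ph$lesions, ph$spleen, organ = "liver")
  expect_identical(fl$organ, "liver")
  expect_true(is.na(fl$sd_ref_m1))  # no BSA without a patient record
  expect_equal(fl$d_ref_cm, fv$d_ref_cm)
})

test_that("single lesion at the reference centroid zeroes all distances", {
  ls <- lesion_set(data.frame(lesion_id = 1L, cx = 10, cy = 20, cz = 30,
                              volume_cm3 = 7))
  ref <- reference_point(c(10, 20, 30))
  d <- distances_to_reference(ref, ls)
  expect_equal(d_reference(d), 0)
  expect_equal(spread(d), 0)
  expect_equal(dmax(ls), 0)
  expect_equal(dbulk(ls), 0)
  expect_equal(tmtv(ls), 7)
})
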