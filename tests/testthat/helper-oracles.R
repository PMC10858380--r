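# Independent reference implementations used as oracles. Deliberately naive
# (explicit loops, no shared code with the package internals).

# Brute-force geometric features from analytic centroids (mm) and volumes
# (cm^3) relative to a reference point (mm). Distances in cm.
oracle_features <- function(centroids, volumes, ref) {
  n <- nrow(centroids)
  d <- numeric(n)
  for (i in seq_len(n))
    d[i] <- sqrt(sum((centroids[i, ] - ref)^2))
  mu <- sum(d) / n
  sp <- sqrt(sum((d - mu)^2) / n) / 10
  dr <- max(d) / 10
  dm <- 0
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dij <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      if (dij > dm) dm <- dij
    }
    dm <- dm / 10
  }
  db <- 0
  if (n > 1) {
    bulk <- 1L
    for (i in seq_len(n)) if (volumes[i] > volumes[bulk]) bulk <- i
    for (j in seq_len(n)) {
      djb <- sqrt(sum((centroids[j, ] - centroids[bulk, ])^2)) / 10
      if (djb > db) db <- djb
    }
  }
  list(spread = sp, d_ref = dr, dmax = dm, dbulk = db, tmtv = sum(volumes))
}

# Breadth-first flood fill component labeling; returns voxel counts sorted
# decreasing. Reference for the graph-based production implementation.
oracle_components <- function(vox, connectivity = 26) {
  d <- dim(vox)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  deg <- rowSums(abs(offs))
  offs <- offs[deg <= switch(as.character(connectivity),
                             "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  visited <- array(FALSE, dim = d)
  counts <- integer(0)
  fg <- which(vox > 0)
  for (s in fg) {
    if (visited[s]) next
    queue <- arrayInd(s, d)
    visited[s] <- TRUE
    size <- 0L
    while (nrow(queue) > 0L) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        nb <- cur + offs[r, ]
        if (any(nb < 1L) || any(nb > d)) next
        lin <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
        if (vox[lin] > 0 && !visited[lin]) {
          visited[lin] <- TRUE
          queue <- rbind(queue, nb)
        }
      }
    }
    counts <- c(counts, size)
  }
  sort(counts, decreasing = TRUE)
}

# Exhaustive Harrell concordance: comparable pairs are (i, j) with an event
# for i strictly before j's time; ties in risk count 1/2.
oracle_concordance <- function(risk, times, events) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (events[i] == 1 && times[i] < times[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# Random analytic lesion configuration inside a 96^3 grid at `spacing` mm.
random_lesion_config <- function(max_lesions = 10, spacing = 4) {
  n <- sample.int(max_lesions, 1)
  extent <- 95 * spacing
  centroids <- matrix(runif(3 * n, 0.1 * extent, 0.9 * extent), ncol = 3)
  volumes <- runif(n, 0.5, 120)
  ref <- runif(3, 0.2 * extent, 0.8 * extent)
  list(centroids = centroids, volumes = volumes, ref = ref)
}

lesion_set_from_config <- function(cfg) {
  lesion_set(data.frame(lesion_id = seq_len(nrow(cfg$centroids)),
                        cx = cfg$centroids[, 1], cy = cfg$centroids[, 2],
                        cz = cfg$centroids[, 3],
                        volume_cm3 = cfg$volumes))
}

# Uniform random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Small two-lesion phantom with an optional spleen satellite blob.
demo_phantom <- function(satellite = FALSE) {
  sat <- if (satellite)
    data.frame(cx = 85, cy = 85, cz = 85, radius_mm = 3) else NULL
  spec <- phantom_spec(
    grid_shape = c(48, 48, 48), spacing = c(2, 2, 2),
    spleen = list(center = c(40, 40, 40), radii = c(12, 16, 20)),
    lesions = data.frame(cx = c(70, 30), cy = c(60, 70), cz = c(60, 30),
                         radius_mm = c(10, 8), label = 1:2),
    satellites = sat)
  make_phantom(spec)
}
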