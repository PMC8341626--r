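# Independent oracles and small fixture builders used across the suite.

# Exhaustive shear-and-project variance maximizer over an angle grid:
# shear each row by -tan(theta) * (row - center), column-average over fully
# covered columns, return the variance per angle. Independent of the
# package's rotation-binned Radon sampler.
shear_project_objective <- function(K, angles_deg) {
  K <- K - mean(K)
  nr <- nrow(K); nc <- ncol(K)
  vc <- (nr + 1) / 2
  vapply(angles_deg, function(a) {
    sl <- tan(a * pi / 180)
    sheared <- matrix(NA_real_, nr, nc)
    for (r in seq_len(nr)) {
      sheared[r, ] <- approx(seq_len(nc), K[r, ],
                             xout = seq_len(nc) + sl * (r - vc),
                             rule = 1)$y
    }
    cover <- colSums(!is.na(sheared))
    full <- cover >= nr / 2
    if (sum(full) < 2) return(0)
    var(colMeans(sheared[, full, drop = FALSE], na.rm = TRUE))
  }, numeric(1))
}

shear_project_angle <- function(K, angles_deg) {
  obj <- shear_project_objective(K, angles_deg)
  best <- which(obj == max(obj))
  angles_deg[best[which.min(abs(angles_deg[best]))]]
}

# Clean synthetic stripe kymograph with the given slope (columns per row).
# The stripe pattern is an aperiodic smoothed random profile, like a real
# RBC train: a periodic pattern would alias to several angles.
stripe_kymograph <- function(nr, nc, slope, noise_sd = 0, seed = 1) {
  set.seed(seed + 1000)
  span <- nc + ceiling(abs(slope) * nr) + 10
  prof <- stats::filter(rnorm(2 * span), rep(1 / 5, 5), circular = TRUE)
  prof <- 100 + 40 * as.numeric(prof) / sd(prof)
  off <- span / 2
  k <- matrix(0, nr, nc)
  for (v in seq_len(nr)) {
    pos <- seq_len(nc) - slope * v + off
    k[v, ] <- approx(seq_along(prof), prof, xout = pos, rule = 2)$y
  }
  if (noise_sd > 0) {
    set.seed(seed)
    k <- k + rnorm(length(k), 0, noise_sd)
  }
  k
}

# Brute-force nearest-feature-voxel distance (um) from exact positions.
brute_force_vessel_distance <- function(centroids, mask, voxel_size_um) {
  feat <- which(mask, arr.ind = TRUE)
  nd <- length(dim(mask))
  sp <- if (nd == 3) voxel_size_um[c("y", "x", "z")] else
    voxel_size_um[c("y", "x")]
  fy <- (feat[, 1] - 0.5) * sp[1]
  fx <- (feat[, 2] - 0.5) * sp[2]
  if (nd == 3) fz <- (feat[, 3] - 0.5) * sp[3]
  vapply(seq_len(nrow(centroids)), function(i) {
    d2 <- (fx - centroids$x_um[i])^2 + (fy - centroids$y_um[i])^2
    if (nd == 3) d2 <- d2 + (fz - centroids$z_um[i])^2
    sqrt(min(d2))
  }, numeric(1))
}

# Small marrow phantom configuration used by several tests.
small_marrow_config <- function(seed = 1, cell_count = 25, ...) {
  phantom_config(volume_um = c(x = 50, y = 50, z = 14),
                 cell_count = cell_count, seed = seed, ...)
}

# Render a uniform-background image with dark discs (matrix fixture).
disc_image <- function(nr, nc, centers, radius, bg = 200, fg = 40) {
  img <- matrix(bg, nr, nc)
  for (k in seq_len(nrow(centers))) {
    d <- sqrt(outer((seq_len(nr) - centers[k, 1])^2,
                    (seq_len(nc) - centers[k, 2])^2, "+"))
    img[d <= radius] <- fg
  }
  img
}

# Match each truth centroid to the nearest detected centroid (um).
nearest_match_distances <- function(truth, detected) {
  vapply(seq_len(nrow(truth)), function(i) {
    min(sqrt((detected$x_um - truth$x_um[i])^2 +
               (detected$y_um - truth$y_um[i])^2 +
               (detected$z_um - truth$z_um[i])^2))
  }, numeric(1))
}

# Map each detected vessel segment to its nearest truth path and align the
# sign of the estimated speed with the truth path orientation.
match_segments_to_paths <- function(segments, estimates, scene) {
  do.call(rbind, lapply(seq_along(segments), function(i) {
    sg <- segments[[i]]
    mid <- colMeans(sg$polyline)
    d <- vapply(scene$truth_paths, function(rp)
      min(sqrt(rowSums(sweep(rp$points, 2, mid)^2))), numeric(1))
    pid <- which.min(d)
    segdir <- sg$polyline[nrow(sg$polyline), ] - sg$polyline[1, ]
    pp <- scene$truth_paths[[pid]]$points
    pdir <- pp[nrow(pp), ] - pp[1, ]
    sgn <- sign(sum(segdir * pdir))
    data.frame(segment_id = sg$id, path_id = pid,
               est_um_s = estimates$speed_um_s[i] * sgn,
               truth_um_s = scene$truth_speeds$speed_um_s[pid],
               measured = estimates$measured[i])
  }))
}
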