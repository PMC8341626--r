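#' Phantom configuration
#'
#' Parameters of the synthetic negative-contrast scene generator. The
#' defaults describe a calvarial-marrow-like field: a bright dye-filled
#' interstitium (level 200 of 8 bits) packed with dark, roughly spherical
#' cells (level 40) whose radii are drawn from N(5, 1) um with a 3 um floor,
#' in a 100 x 100 x 20 um^3 volume sampled at 0.5 x 0.5 x 0.34 um voxels.
#'
#' Marrow cells are tightly packed and deformable, so the generator permits
#' spheres to interpenetrate up to \code{overlap_tolerance} (fraction of the
#' summed radii) and assigns contested voxels to the nearest cell surface,
#' preserving a thin bright interstitial film (\code{film_um}) on every
#' contact surface -- the sub-resolution dye-filled cleft that makes packed
#' cells separable in real negative-contrast images.
#'
#' @param volume_um named vector \code{c(x=, y=, z=)}, physical volume (um).
#'   For 2D flow series give \code{c(x=, y=)}.
#' @param voxel_size_um named voxel sizes (um).
#' @param cell_count number of cells to place.
#' @param cell_radius_um \code{c(mean=, sd=, min=)} of the radius
#'   distribution (truncated normal, um).
#' @param overlap_tolerance allowed interpenetration: minimum center
#'   separation is \code{(r_i + r_j) * (1 - overlap_tolerance)}.
#' @param film_um thickness of the bright interstitial film preserved
#'   between contacting cells (um).
#' @param edge_softness_um half-width of the anti-aliasing ramp at object
#'   boundaries (um).
#' @param vessel_paths list of vessels, each \code{list(points =}
#'   n x 2 or n x 3 \code{matrix of (x, y[, z]) um, radius_um = )}.
#' @param interstitium_level,cell_level,vessel_level intensity levels;
#'   \code{interstitium_level > cell_level} is required.
#' @param noise_sd Gaussian noise standard deviation (intensity units);
#'   default 5\% of \code{interstitium_level}.
#' @param poisson_noise apply Poisson resampling of the clean intensities
#'   before Gaussian noise.
#' @param bleaching_rate per-frame bleaching rate applied to the cell
#'   compartment by [generate_bleaching_series()].
#' @param flow_speeds_um_s per-vessel flow speed: a numeric vector (one
#'   constant speed per path, signed along the path orientation) or a list
#'   whose elements are either scalars or two-column matrices
#'   \code{(t_start_s, speed_um_s)} defining a stepwise profile.
#' @param rbc_radius_um,rbc_spacing_um radius and along-path spacing of the
#'   flowing dark discs.
#' @param frame_rate_fps,duration_s temporal sampling of flow series.
#' @param seed integer; fully determines the generated scene.
#' @return A named list of class \code{phantom_config}.
#' @export
phantom_config <- function(volume_um = c(x = 100, y = 100, z = 20),
                           voxel_size_um = c(x = 0.5, y = 0.5, z = 0.34),
                           cell_count = 200,
                           cell_radius_um = c(mean = 5, sd = 1, min = 3),
                           overlap_tolerance = 0.35,
                           film_um = 0.8,
                           edge_softness_um = 0.5,
                           vessel_paths = NULL,
                           interstitium_level = 200,
                           cell_level = 40,
                           vessel_level = 220,
                           noise_sd = 0.05 * interstitium_level,
                           poisson_noise = FALSE,
                           bleaching_rate = 0,
                           flow_speeds_um_s = NULL,
                           rbc_radius_um = 2.5,
                           rbc_spacing_um = 20,
                           frame_rate_fps = 120,
                           duration_s = 2,
                           seed = 1) {
  stopifnot(interstitium_level > cell_level,
            all(cell_radius_um[c("mean", "min")] > 0),
            overlap_tolerance >= 0, overlap_tolerance < 1,
            bleaching_rate >= 0, bleaching_rate < 1)
  cfg <- as.list(environment())
  class(cfg) <- "phantom_config"
  cfg
}

#' Flow-series phantom configuration
#'
#' [phantom_config()] preset for a 2D vascular network imaged at video rate:
#' a 256 x 128 um field at 1 um pixels, five straight vessel segments
#' (radius 4 um) carrying dark discs at configurable speeds, 120 fps for
#' 2 s. Plasma is bright (level 220), the surrounding tissue dimmer (level
#' 100), flowing cells dark (level 40).
#'
#' @param speeds_um_s signed speeds, one per vessel segment (or a list with
#'   stepwise profiles, see [phantom_config()]).
#' @param frame_rate_fps,duration_s temporal sampling.
#' @param seed integer seed.
#' @param ... further overrides passed to [phantom_config()].
#' @return A \code{phantom_config}.
#' @export
flow_phantom_config <- function(speeds_um_s = c(0, 100, 250, 500, 900),
                                frame_rate_fps = 120, duration_s = 2,
                                seed = 1, ...) {
  n <- if (is.list(speeds_um_s)) length(speeds_um_s) else length(speeds_um_s)
  ys <- seq(16, 112, length.out = n)
  slants <- rep_len(c(0, 3, -3, 3, -3), n)
  paths <- lapply(seq_len(n), function(i) {
    x <- c(14, 242)
    y <- ys[i] + c(-1, 1) * tan(slants[i] * pi / 180) * diff(x) / 2
    list(points = cbind(x = x, y = y), radius_um = 4)
  })
  phantom_config(volume_um = c(x = 256, y = 128),
                 voxel_size_um = c(x = 1, y = 1),
                 cell_count = 0,
                 vessel_paths = paths,
                 interstitium_level = 100, vessel_level = 220,
                 cell_level = 40,
                 flow_speeds_um_s = speeds_um_s,
                 frame_rate_fps = frame_rate_fps, duration_s = duration_s,
                 seed = seed, ...)
}

# ---- geometry helpers -------------------------------------------------------

# Resample a polyline (n x k um) to ~`step` um spacing; returns points and
# cumulative arc length.
resample_polyline <- function(points, step) {
  seg <- diff(points)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  out <- sapply(seq_len(ncol(points)), function(j)
    approx(cum, points[, j], xout = s, rule = 2)$y)
  list(points = matrix(out, ncol = ncol(points)), arc = s, length = total)
}

# Point on a polyline at arc position s (recycled modulo total length).
polyline_point <- function(rp, s) {
  s <- s %% rp$length
  out <- vapply(seq_len(ncol(rp$points)), function(j)
    approx(rp$arc, rp$points[, j], xout = s, rule = 2)$y,
    numeric(length(s)))
  matrix(out, nrow = length(s))
}

# Minimum distance from points (m x k) to a polyline (n x k), exact
# point-to-segment distances.
dist_to_polyline <- function(pts, poly) {
  pts <- matrix(pts, ncol = ncol(poly))
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a)
    t <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(pmax(ap %*% ab / len2, 0), 1)
    proj <- outer(drop(t), ab)
    d2 <- pmin(d2, rowSums((ap - proj)^2))
  }
  sqrt(d2)
}

# Binary tube mask: voxels whose center lies within radius of any path.
# dims/voxel in (y, x[, z]) array order; paths in (x, y[, z]) um.
rasterize_vessels <- function(shape, voxel_yxz, paths) {
  mask <- array(FALSE, shape)
  if (is.null(paths) || !length(paths)) return(mask)
  nd <- length(shape)
  feat <- array(FALSE, shape)
  for (p in paths) {
    rp <- resample_polyline(p$points, min(voxel_yxz) / 4)
    pts <- rp$points # (x, y[, z]) um
    iy <- pmin(pmax(round(um_to_index(pts[, 2], voxel_yxz[1])), 1), shape[1])
    ix <- pmin(pmax(round(um_to_index(pts[, 1], voxel_yxz[2])), 1), shape[2])
    if (nd == 3) {
      iz <- pmin(pmax(round(um_to_index(pts[, 3], voxel_yxz[3])), 1), shape[3])
      feat[cbind(iy, ix, iz)] <- TRUE
    } else feat[cbind(iy, ix)] <- TRUE
  }
  d2 <- cpp_edt_sq(feat, as.integer(shape), as.numeric(voxel_yxz))
  radii <- vapply(paths, `[[`, numeric(1), "radius_um")
  array(sqrt(d2) <= max(radii), shape)
}

# ---- cell placement ---------------------------------------------------------

draw_radii <- function(n, par) {
  r <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rnorm(1, par["mean"], par["sd"])
    while (ri < par["min"]) ri <- rnorm(1, par["mean"], par["sd"])
    r[i] <- ri
  }
  r
}

place_cells <- function(cfg, max_attempts_per_cell = 20000) {
  vol <- cfg$volume_um
  n <- cfg$cell_count
  if (n == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), radius_um = numeric(0)))
  radii <- draw_radii(n, cfg$cell_radius_um)
  tot_cell_vol <- sum(4 / 3 * pi * radii^3)
  if (tot_cell_vol > 0.8 * prod(vol[c("x", "y", "z")]))
    stop("infeasible packing: requested cell volume exceeds 80% of the ROI")
  centers <- matrix(NA_real_, n, 3)
  acc_r <- numeric(0)
  sep_fac <- 1 - cfg$overlap_tolerance
  for (k in seq_len(n)) {
    r <- radii[k]
    placed <- FALSE
    for (a in seq_len(max_attempts_per_cell)) {
      # cells are wholly inside laterally but may be clipped by the top and
      # bottom faces of the optical section (z margin r/2), as in a real
      # 20 um imaging stack
      cand <- c(runif(1, r, vol["x"] - r),
                runif(1, r, vol["y"] - r),
                runif(1, r / 2, vol["z"] - r / 2))
      if (k > 1) {
        d <- sqrt(colSums((t(centers[seq_len(k - 1), , drop = FALSE]) - cand)^2))
        if (any(d < (acc_r + r) * sep_fac)) next
      }
      ok <- TRUE
      for (p in cfg$vessel_paths %||% list()) {
        if (dist_to_polyline(cand, p$points) < p$radius_um + 0.5 * r) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      centers[k, ] <- cand
      acc_r <- c(acc_r, r)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible packing: could not place cell ", k, " of ", n,
           " after ", max_attempts_per_cell, " attempts")
  }
  data.frame(x_um = centers[, 1], y_um = centers[, 2], z_um = centers[, 3],
             radius_um = radii)
}

#' Sample a ground-truth cell packing
#'
#' Draws the cell centers and radii that [generate_marrow_phantom()] would
#' render for the same configuration and seed (the placement is the first
#' consumer of the random stream), without rasterizing the volume. Useful
#' for fast statistical replicates over the generator's ground truth.
#'
#' @param config a [phantom_config()].
#' @return data.frame with \code{x_um, y_um, z_um, radius_um, diameter_um}.
#' @export
sample_cell_packing <- function(config) {
  cells <- with_seed(config$seed, place_cells(config))
  cells$diameter_um <- 2 * cells$radius_um
  cells
}

# ---- rendering --------------------------------------------------------------

phantom_shape <- function(cfg) {
  vol <- cfg$volume_um
  ax <- intersect(c("y", "x", "z"), names(vol))
  shape <- as.integer(round(vol[ax] / cfg$voxel_size_um[ax]))
  names(shape) <- ax
  shape
}

# Stamp soft spheres; returns list(img, cell_mask, nearest margin arrays).
render_cells <- function(cfg, cells, shape) {
  vox <- cfg$voxel_size_um[c("y", "x", "z")]
  m1 <- array(Inf, shape)
  m2 <- array(Inf, shape)
  w <- cfg$edge_softness_um
  pad <- cfg$film_um + w + max(vox)
  for (k in seq_len(nrow(cells))) {
    ctr <- c(cells$y_um[k], cells$x_um[k], cells$z_um[k])
    r <- cells$radius_um[k]
    lo <- pmax(1L, floor(um_to_index(ctr - r - pad, vox)))
    hi <- pmin(shape, ceiling(um_to_index(ctr + r + pad, vox)))
    iy <- lo[1]:hi[1]; ix <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dy2 <- (index_to_um(iy, vox[1]) - ctr[1])^2
    dx2 <- (index_to_um(ix, vox[2]) - ctr[2])^2
    dz2 <- (index_to_um(iz, vox[3]) - ctr[3])^2
    d <- sqrt(outer(outer(dy2, dx2, "+"), dz2, "+"))
    md <- d - r
    m1b <- m1[iy, ix, iz]; m2b <- m2[iy, ix, iz]
    new1 <- pmin(m1b, md)
    new2 <- pmin(m2b, pmax(m1b, md))
    m1[iy, ix, iz] <- new1
    m2[iy, ix, iz] <- new2
  }
  inside <- pmin(pmax(0.5 - m1 / (2 * w), 0), 1)
  gap <- m2 - m1
  gap[!is.finite(gap)] <- Inf # untouched voxels (both margins infinite)
  sep <- pmin(pmax((gap - cfg$film_um) / (2 * w) + 0.5, 0), 1)
  dark <- inside * sep
  dark[inside == 0] <- 0
  img <- cfg$interstitium_level +
    (cfg$cell_level - cfg$interstitium_level) * dark
  list(img = img, cell_mask = (m1 < 0) & ((m2 - m1) > cfg$film_um))
}

add_noise <- function(img, cfg) {
  if (cfg$poisson_noise) img <- array(rpois(length(img), pmax(img, 0)), dim(img))
  if (cfg$noise_sd > 0) img <- img + rnorm(length(img), 0, cfg$noise_sd)
  img
}

quantize <- function(img, bit_depth = 8L) {
  a <- array(as.integer(pmin(pmax(round(img), 0), 2^bit_depth - 1)), dim(img))
  a
}

#' Generate a synthetic marrow volume with ground truth
#'
#' Renders dark soft-edged spheres (unlabeled cells) in a bright interstitium,
#' with optional bright vessel tubes, then applies the configured noise. The
#' scene is fully determined by \code{config$seed}.
#'
#' @param config a [phantom_config()].
#' @param cells optional data.frame (\code{x_um, y_um, z_um, radius_um}) of
#'   cells to render instead of sampling a new packing; used for paired
#'   scenes that share a packing (e.g. a post-treatment scene rendered
#'   after removing cells from the pre-treatment truth).
#' @return A \code{phantom_scene}: list with \code{stack} (an [image_stack],
#'   axes \code{yxz}), \code{truth_cells} (centroids, radii and diameters in
#'   um), \code{truth_cell_mask}, \code{truth_vessel_mask}, and
#'   \code{truth_speeds} (\code{NULL} here).
#' @examples
#' cfg <- phantom_config(volume_um = c(x = 30, y = 30, z = 12),
#'                       cell_count = 8, seed = 7)
#' sc <- generate_marrow_phantom(cfg)
#' nrow(sc$truth_cells)
#' @export
generate_marrow_phantom <- function(config, cells = NULL) {
  shape <- phantom_shape(config)
  stopifnot(length(shape) == 3L)
  with_seed(config$seed, {
    if (is.null(cells)) cells <- place_cells(config)
    rc <- render_cells(config, cells, shape)
    img <- rc$img
    vmask <- rasterize_vessels(shape, config$voxel_size_um[c("y", "x", "z")],
                               config$vessel_paths)
    img[vmask] <- config$vessel_level
    cell_mask <- rc$cell_mask & !vmask
    img <- add_noise(img, config)
    stack <- image_stack(quantize(img), "yxz",
                         voxel_size_um = config$voxel_size_um)
    cells$diameter_um <- 2 * cells$radius_um
    structure(list(stack = stack, truth_cells = cells,
                   truth_cell_mask = cell_mask,
                   truth_vessel_mask = vmask, truth_speeds = NULL,
                   config = config),
              class = "phantom_scene")
  })
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat("phantom_scene with", nrow(x$truth_cells %||% data.frame()),
      "truth cells\n")
  print(x$stack)
  if (!is.null(x$truth_speeds)) {
    cat("  truth flow speeds (um/s):",
        paste(signif(x$truth_speeds$speed_um_s, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

speed_profile_fun <- function(sp) {
  if (is.function(sp)) return(sp)
  if (is.matrix(sp)) {
    force(sp)
    return(function(t) sp[findInterval(t, sp[, 1], rightmost.closed = FALSE), 2])
  }
  function(t) rep_len(sp, length(t))
}

#' Generate a synthetic 2D flow time series with ground truth
#'
#' Renders bright plasma-filled vessel tubes on a dimmer background, with
#' trains of dark discs advancing along each vessel path by
#' \code{speed * dt} per frame (anti-aliased sub-voxel stamping; positions
#' wrap around the path). Positive speed means motion along the stored path
#' orientation.
#'
#' @param config a [phantom_config()] (see [flow_phantom_config()]) with 2D
#'   \code{volume_um}, \code{vessel_paths} and \code{flow_speeds_um_s}.
#' @return A \code{phantom_scene} whose \code{stack} has axes \code{yxt},
#'   with \code{truth_speeds} (data.frame \code{path_id, speed_um_s} at
#'   t = 0, with the full per-frame speed matrix in attribute
#'   \code{"speed_by_frame"}) and \code{truth_vessel_mask}.
#' @export
generate_flow_series <- function(config) {
  shape <- phantom_shape(config)
  stopifnot(length(shape) == 2L)
  paths <- config$vessel_paths
  if (is.null(paths) || !length(paths)) stop("flow series needs vessel_paths")
  speeds <- config$flow_speeds_um_s
  if (is.null(speeds)) stop("flow series needs flow_speeds_um_s")
  if (!is.list(speeds)) speeds <- as.list(speeds)
  stopifnot(length(speeds) == length(paths))
  dt <- 1 / config$frame_rate_fps
  nt <- max(2L, as.integer(round(config$duration_s * config$frame_rate_fps)))
  vox <- config$voxel_size_um[c("y", "x")]
  w <- config$edge_softness_um

  rps <- lapply(paths, function(p) resample_polyline(p$points, min(vox) / 2))
  funs <- lapply(speeds, speed_profile_fun)
  for (i in seq_along(paths)) {
    vmax <- max(abs(funs[[i]](seq(0, nt - 1) * dt)))
    if (vmax * dt > rps[[i]]$length)
      stop("speed ", vmax, " um/s traverses the whole segment (",
           signif(rps[[i]]$length, 4), " um) in one frame interval")
  }

  with_seed(config$seed, {
    # distance to the vessel axes for a soft-edged bright lumen
    axes_feat <- array(FALSE, shape)
    for (p in paths) {
      rp <- resample_polyline(p$points, min(vox) / 4)
      iy <- pmin(pmax(round(um_to_index(rp$points[, 2], vox[1])), 1), shape[1])
      ix <- pmin(pmax(round(um_to_index(rp$points[, 1], vox[2])), 1), shape[2])
      axes_feat[cbind(iy, ix)] <- TRUE
    }
    dax <- sqrt(cpp_edt_sq(axes_feat, as.integer(shape), as.numeric(vox)))
    rad <- max(vapply(paths, `[[`, numeric(1), "radius_um"))
    lum <- pmin(pmax(0.5 - (dax - rad) / (2 * w), 0), 1)
    base <- config$interstitium_level +
      (config$vessel_level - config$interstitium_level) * lum
    vmask <- dax <= rad

    # initial disc arc positions per path: irregular gaps (+-30% around the
    # nominal spacing), as in a real RBC train; regular spacing would
    # stroboscopically alias with commensurate speed/frame-rate combinations
    discs <- lapply(seq_along(paths), function(i) {
      len <- rps[[i]]$length
      gaps <- runif(ceiling(len / (0.7 * config$rbc_spacing_um)) + 1L,
                    0.7 * config$rbc_spacing_um,
                    1.3 * config$rbc_spacing_um)
      pos <- runif(1, 0, config$rbc_spacing_um) + c(0, cumsum(gaps))
      pos[pos < len]
    })

    out <- array(0L, c(shape, nt))
    rbc <- config$rbc_radius_um
    ygrid <- index_to_um(seq_len(shape[1]), vox[1])
    xgrid <- index_to_um(seq_len(shape[2]), vox[2])
    speed_by_frame <- matrix(0, nt, length(paths))
    for (f in seq_len(nt)) {
      t0 <- (f - 1) * dt
      img <- base
      for (i in seq_along(paths)) {
        v <- funs[[i]](t0)
        speed_by_frame[f, i] <- v
        pos <- polyline_point(rps[[i]], discs[[i]])
        for (j in seq_len(nrow(pos))) {
          cx <- pos[j, 1]; cy <- pos[j, 2]
          iy <- which(abs(ygrid - cy) <= rbc + w)
          ix <- which(abs(xgrid - cx) <= rbc + w)
          if (!length(iy) || !length(ix)) next
          d <- sqrt(outer((ygrid[iy] - cy)^2, (xgrid[ix] - cx)^2, "+"))
          a <- pmin(pmax(0.5 - (d - rbc) / (2 * w), 0), 1)
          img[iy, ix] <- img[iy, ix] * (1 - a) + config$cell_level * a
        }
        discs[[i]] <- (discs[[i]] + v * dt) %% rps[[i]]$length
      }
      img <- add_noise(img, config)
      out[, , f] <- quantize(img)
    }
    stack <- image_stack(out, "yxt", voxel_size_um = config$voxel_size_um,
                         frame_interval_s = dt)
    truth <- data.frame(path_id = seq_along(paths),
                        speed_um_s = speed_by_frame[1, ])
    attr(truth, "speed_by_frame") <- speed_by_frame
    structure(list(stack = stack, truth_cells = NULL,
                   truth_cell_mask = NULL, truth_vessel_mask = vmask,
                   truth_speeds = truth, config = config,
                   truth_paths = rps),
              class = "phantom_scene")
  })
}

#' Apply exponential photobleaching to a compartment of a time series
#'
#' Multiplies intensities inside \code{compartment_mask} by
#' \code{(1 - rate)^(frame - 1)}; voxels outside the mask are untouched.
#'
#' @param stack an [image_stack] whose last axis is \code{t}.
#' @param rate per-frame bleaching rate in \code{[0, 1)}.
#' @param compartment_mask logical array congruent with one frame.
#' @return The bleached [image_stack] (numeric data).
#' @export
apply_bleaching <- function(stack, rate, compartment_mask) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  ti <- axis_index(stack, "t")
  d <- dim(stack$data)
  if (ti != length(d)) stop("t must be the last axis")
  if (!identical(dim(compartment_mask), d[-ti]) &&
      !(is.null(dim(compartment_mask)) && length(compartment_mask) == prod(d[-ti])))
    stop("compartment_mask shape mismatch")
  a <- stack$data * 1.0
  m <- matrix(a, prod(d[-ti]), d[ti])
  idx <- which(as.logical(compartment_mask))
  if (length(idx)) {
    fac <- (1 - rate)^(seq_len(d[ti]) - 1)
    m[idx, ] <- m[idx, ] %*% diag(fac, nrow = d[ti])
  }
  dim(m) <- d
  stack$data <- m
  stack
}

#' Generate a photobleaching time series with ground truth
#'
#' Emulates continuous scanning of a field holding fluorescent-protein
#' labeled cells in a dye-filled interstitium: one noiseless mid-depth
#' section of a marrow phantom is rendered, the cell compartment is set to
#' a bright label level (positive contrast, as for an actin reporter), the
#' section is replicated over time, the cell compartment is bleached at
#' \code{config$bleaching_rate} per frame (the interstitial dye is
#' continuously replenished by interstitial flow and does not bleach), and
#' independent noise is added per frame.
#'
#' @param config a [phantom_config()] with \code{bleaching_rate} set.
#' @param n_frames number of frames.
#' @param label_level intensity of the labeled cell compartment at frame 0
#'   (default 0.9 x interstitium level).
#' @return list with \code{stack} (axes \code{yxt}),
#'   \code{truth_cell_mask}, \code{truth_interstitium_mask}, \code{rate}.
#' @export
generate_bleaching_series <- function(config, n_frames = 50,
                                      label_level = 0.9 * config$interstitium_level) {
  base_cfg <- config
  base_cfg$noise_sd <- 0
  base_cfg$poisson_noise <- FALSE
  scene <- generate_marrow_phantom(base_cfg)
  zmid <- ceiling(dim(scene$stack$data)[3] / 2)
  frame0 <- scene$stack$data[, , zmid] * 1.0
  cmask <- scene$truth_cell_mask[, , zmid]
  frame0[cmask] <- label_level
  imask <- !cmask & !scene$truth_vessel_mask[, , zmid]
  a <- array(rep(frame0, n_frames), c(dim(frame0), n_frames))
  stack <- image_stack(a, "yxt", voxel_size_um = config$voxel_size_um,
                       frame_interval_s = 1 / config$frame_rate_fps)
  stack <- apply_bleaching(stack, config$bleaching_rate, cmask)
  with_seed(config$seed + 1L, {
    stack$data <- stack$data + rnorm(length(stack$data), 0, config$noise_sd)
  })
  stack$data <- pmax(stack$data, 0)
  list(stack = stack, truth_cell_mask = cmask,
       truth_interstitium_mask = imask, rate = config$bleaching_rate)
}
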