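# Motion mapping and kymograph (digital line scan) velocimetry.

#' Temporal standard-deviation motion map
#'
#' Per-pixel sample standard deviation over the \code{t} axis. Pixels with
#' high standard deviation mark moving cells (vessel lumina, migration
#' sites); static regions stay dark. Invariant to frame order.
#'
#' @param series an [image_stack] with \code{t} as last axis (>= 2 frames).
#' @return An [image_stack] one rank lower (class also
#'   \code{motion_map}).
#' @export
std_dev_map <- function(series) {
  ti <- axis_index(series, "t")
  d <- dim(series$data)
  if (ti != length(d)) stop("t must be the last axis")
  if (d[ti] < 2L) stop("need at least 2 frames")
  n <- d[ti]
  m <- matrix(series$data * 1.0, prod(d[-ti]), n)
  mu <- rowMeans(m)
  s2 <- (rowSums(m^2) - n * mu^2) / (n - 1)
  out <- sqrt(pmax(s2, 0))
  dim(out) <- d[-ti]
  res <- image_stack(out, series$axes[-ti],
                     voxel_size_um = series$voxel_size_um,
                     bit_depth = series$bit_depth)
  class(res) <- c("motion_map", class(res))
  res
}

#' Digital line scan (kymograph) along a vessel segment
#'
#' For each frame, intensities are sampled along the segment polyline at
#' arc steps of \code{ds_um} (default the smaller pixel pitch) by bilinear
#' interpolation, averaged across \code{line_width_px} perpendicular
#' offsets, and stacked over time: rows are time (top to bottom), columns
#' arc position along the stored orientation. A stationary dark cell shows
#' as a vertical dark stripe; a moving cell as a slanted stripe whose slope
#' encodes its speed.
#'
#' @param series an [image_stack] with axes \code{yxt}.
#' @param segment a \code{vessel_segment} (from
#'   [select_vessel_segments()]) or an n x 2 matrix of (x, y) um.
#' @param line_width_px number of perpendicular offsets averaged (odd,
#'   default 3).
#' @param ds_um arc step (um).
#' @return Object of class \code{kymograph}: \code{data} (time x position),
#'   \code{ds_um}, \code{dt_s}, \code{segment_id}, \code{line_width_px}.
#' @export
digital_line_scan <- function(series, segment, line_width_px = 3,
                              ds_um = NULL) {
  stopifnot(identical(series$axes, c("y", "x", "t")))
  poly <- if (inherits(segment, "vessel_segment")) segment$polyline else segment
  seg_id <- if (inherits(segment, "vessel_segment")) segment$id else NA_integer_
  vox <- series$voxel_size_um[c("x", "y")]
  ds <- ds_um %||% min(vox)
  rp <- resample_polyline(poly, ds)
  pts <- rp$points # (x, y) um
  np <- nrow(pts)
  # unit tangents and normals
  tg <- rbind(pts[2, ] - pts[1, ],
              (pts[seq(3, np), , drop = FALSE] -
                 pts[seq(1, np - 2), , drop = FALSE]) / 2,
              pts[np, ] - pts[np - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  nrm <- cbind(-tg[, 2], tg[, 1])
  offs <- (seq_len(line_width_px) - (line_width_px + 1) / 2) * min(vox)
  sx <- outer(pts[, 1], rep(1, line_width_px)) +
    outer(nrm[, 1], rep(1, line_width_px)) * matrix(offs, np, line_width_px, byrow = TRUE)
  sy <- outer(pts[, 2], rep(1, line_width_px)) +
    outer(nrm[, 2], rep(1, line_width_px)) * matrix(offs, np, line_width_px, byrow = TRUE)
  d <- dim(series$data)
  iy <- um_to_index(sy, series$voxel_size_um["y"])
  ix <- um_to_index(sx, series$voxel_size_um["x"])
  if (min(iy) < 0.5 || max(iy) > d[1] + 0.5 ||
      min(ix) < 0.5 || max(ix) > d[2] + 0.5)
    stop("segment (with line width) exits the field of view")
  idx <- cbind(as.vector(iy), as.vector(ix))
  nt <- d[3]
  out <- matrix(0, nt, np)
  for (f in seq_len(nt)) {
    vals <- interp_array(series$data[, , f] * 1.0, idx)
    out[f, ] <- rowMeans(matrix(vals, np, line_width_px))
  }
  structure(list(data = out, ds_um = ds, dt_s = series$frame_interval_s,
                 segment_id = seg_id, line_width_px = line_width_px),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph (segment %s): %d frames x %d positions, ds=%.3g um, dt=%.4g s\n",
              x$segment_id, nrow(x$data), ncol(x$data), x$ds_um, x$dt_s))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  image(t(x$data)[, rev(seq_len(nrow(x$data)))],
        col = gray(seq(0, 1, length.out = 256)),
        xlab = "arc position", ylab = "time", axes = FALSE, ...)
  invisible(x)
}

# Radon projection-variance objective over an angle grid. Returns the
# objective per angle.
radon_objective <- function(K, angles_deg) {
  nr <- nrow(K); nc <- ncol(K)
  U <- matrix(seq_len(nc) - (nc + 1) / 2, nr, nc, byrow = TRUE)
  V <- matrix(seq_len(nr) - (nr + 1) / 2, nr, nc)
  u <- as.vector(U); v <- as.vector(V); k <- as.vector(K)
  vapply(angles_deg, function(a) {
    th <- a * pi / 180
    p <- round(u * cos(th) - v * sin(th))
    p <- p - min(p) + 1L
    nb <- max(p)
    cnts <- tabulate(p, nbins = nb)
    present <- which(cnts > 0)
    sums <- unname(rowsum(k, p)[, 1]) # rows follow sort(unique(p)) = present
    keep <- cnts[present] >= 0.5 * max(cnts)
    if (sum(keep) < 2) return(0)
    # count-weighted variance of the per-bin means: each bin's sampling
    # noise then contributes equally, so partially filled bins do not
    # inflate the objective at off-stripe angles
    w <- cnts[present][keep]
    prof <- (sums / cnts[present])[keep]
    mw <- sum(w * prof) / sum(w)
    sum(w * (prof - mw)^2) / sum(w)
  }, numeric(1))
}

#' Stripe-angle estimation by Radon transform
#'
#' Finds the angle (from vertical) that maximizes the variance of the Radon
#' projection profile of the mean-subtracted kymograph: projecting along
#' the stripe direction concentrates the stripes into sharp peaks, so the
#' projection variance peaks at the stripe angle. The slope in px/frame is
#' \code{tan(angle)}. Ties are broken toward the smaller absolute angle.
#'
#' @param kymo a [digital_line_scan()] kymograph (>= 8 rows) or matrix.
#' @param angle_step_deg grid step (default 0.25 degrees).
#' @param angle_max_deg grid bound, exclusive of horizontal (default
#'   89.75).
#' @param confidence_min peak-sharpness threshold below which no estimate
#'   is reported.
#' @return list: \code{angle_deg}, \code{slope_px_per_frame},
#'   \code{confidence}, \code{ok} (FALSE for flat/featureless kymographs),
#'   \code{objective} (data.frame angle/value).
#' @export
radon_slope <- function(kymo, angle_step_deg = 0.25, angle_max_deg = 89.75,
                        confidence_min = 3) {
  K <- if (inherits(kymo, "kymograph")) kymo$data else kymo
  if (nrow(K) < 8) stop("kymograph needs at least 8 rows")
  K <- K - mean(K)
  if (all(abs(K) < 1e-12)) {
    return(list(angle_deg = NA_real_, slope_px_per_frame = NA_real_,
                confidence = 0, ok = FALSE, objective = NULL))
  }
  angles <- seq(-angle_max_deg, angle_max_deg, by = angle_step_deg)
  obj <- radon_objective(K, angles)
  # ties toward smaller |angle|
  best <- which(obj == max(obj))
  best <- best[which.min(abs(angles[best]))]
  med <- median(obj)
  iqr <- quantile(obj, 0.75, names = FALSE) - quantile(obj, 0.25, names = FALSE)
  conf <- (obj[best] - med) / (iqr + .Machine$double.eps)
  list(angle_deg = angles[best],
       slope_px_per_frame = tan(angles[best] * pi / 180),
       confidence = unname(conf), ok = conf >= confidence_min,
       objective = data.frame(angle_deg = angles, value = obj))
}

#' Convert a kymograph stripe slope to a signed speed
#'
#' \code{speed = slope * ds / dt * orientation_sign}; positive along the
#' stored segment orientation.
#'
#' @param slope_px_per_frame stripe slope (columns per row).
#' @param ds_um,dt_s kymograph calibration (> 0).
#' @param orientation_sign +1 or -1.
#' @return Speed in um/s.
#' @export
speed_from_slope <- function(slope_px_per_frame, ds_um, dt_s,
                             orientation_sign = 1) {
  stopifnot(ds_um > 0, dt_s > 0)
  slope_px_per_frame * ds_um / dt_s * orientation_sign
}

#' Largest speed reportable from a kymograph
#'
#' The fastest stripe that still crosses the kymograph over at least
#' \code{min_rows} rows: \code{v_max = segment_length_um * frame_rate_fps /
#' min_rows}. Estimates above this are censored, never extrapolated.
#'
#' @param frame_rate_fps frames per second (> 0).
#' @param segment_length_um segment length (um, > 0).
#' @param min_rows minimum number of rows a stripe must span (default 3).
#' @return Speed bound in um/s.
#' @export
max_reportable_speed <- function(frame_rate_fps, segment_length_um,
                                 min_rows = 3) {
  stopifnot(frame_rate_fps > 0, segment_length_um > 0, min_rows > 0)
  segment_length_um * frame_rate_fps / min_rows
}

#' Rolling velocity time course from a kymograph
#'
#' Applies [radon_slope()] + [speed_from_slope()] to sliding row windows
#' (e.g. one estimate every 0.1 s at 30 fps).
#'
#' @param kymo a [digital_line_scan()] kymograph.
#' @param window_s window length in seconds (>= 3 frames).
#' @param step_s step between window starts (<= window).
#' @param orientation_sign sign convention passed through.
#' @param ... passed to [radon_slope()].
#' @return data.frame \code{t_s} (window center), \code{speed_um_s} (NA
#'   where no confident estimate), \code{confidence}.
#' @export
rolling_velocity_series <- function(kymo, window_s, step_s,
                                    orientation_sign = 1, ...) {
  dt <- kymo$dt_s
  w <- max(8L, as.integer(round(window_s / dt)))
  st <- max(1L, as.integer(round(step_s / dt)))
  if (st > w) stop("step exceeds window")
  nr <- nrow(kymo$data)
  if (w > nr) stop("window exceeds kymograph length")
  starts <- seq(1L, nr - w + 1L, by = st)
  res <- lapply(starts, function(s) {
    sub <- kymo$data[s:(s + w - 1L), , drop = FALSE]
    r <- radon_slope(sub, ...)
    sp <- if (isTRUE(r$ok))
      speed_from_slope(r$slope_px_per_frame, kymo$ds_um, dt,
                       orientation_sign) else NA_real_
    data.frame(t_s = (s - 1 + (w - 1) / 2) * dt, speed_um_s = sp,
               confidence = r$confidence)
  })
  do.call(rbind, res)
}

#' Flow profile of a 2D vascular network
#'
#' One signed flow estimate per vessel segment: digital line scan, Radon
#' slope, censoring at the reportable-speed bound. Segments without a
#' confident stripe pattern are reported as unmeasured (NA), not as zero.
#'
#' @param series an [image_stack] with axes \code{yxt}.
#' @param network a \code{vessel_network} from [build_vessel_network()],
#'   or a list of segments.
#' @param params list: \code{line_width_px} (3), \code{angle_step_deg}
#'   (0.25), \code{confidence_min} (3), \code{min_rows} (3).
#' @return list with \code{estimates} (data.frame \code{segment_id,
#'   speed_um_s, angle_deg, confidence, censored, measured,
#'   length_um}) and \code{speed_map} (matrix, NA off-vessel).
#' @export
flow_profile_map <- function(series, network, params = list()) {
  segs <- if (inherits(network, "vessel_network")) network$segments else network
  if (!length(segs)) stop("empty vessel network")
  lw <- params$line_width_px %||% 3
  astep <- params$angle_step_deg %||% 0.25
  cmin <- params$confidence_min %||% 3
  min_rows <- params$min_rows %||% 3
  fps <- 1 / series$frame_interval_s
  d <- dim(series$data)
  smap <- matrix(NA_real_, d[1], d[2])
  rows <- lapply(segs, function(sg) {
    ky <- digital_line_scan(series, sg, line_width_px = lw)
    r <- radon_slope(ky, angle_step_deg = astep, confidence_min = cmin)
    vmax <- max_reportable_speed(fps, sg$length_um, min_rows)
    measured <- isTRUE(r$ok)
    sp <- ang <- NA_real_
    censored <- FALSE
    if (measured) {
      sp <- speed_from_slope(r$slope_px_per_frame, ky$ds_um, ky$dt_s)
      ang <- r$angle_deg
      if (abs(sp) > vmax) { sp <- sign(sp) * vmax; censored <- TRUE }
      smap[sg$polyline_px] <<- sp
    }
    data.frame(segment_id = sg$id, speed_um_s = sp, angle_deg = ang,
               confidence = r$confidence, censored = censored,
               measured = measured, length_um = sg$length_um)
  })
  list(estimates = do.call(rbind, rows), speed_map = smap)
}

#' Photobleaching kinetics per compartment
#'
#' Per-frame mean intensity inside each compartment mask, normalized to the
#' first frame, with an optional single-exponential fit
#' \code{I_t = (1 - rate)^t} returning the per-frame rate. In vivo the
#' interstitial dye is replenished by interstitial flow and stays flat
#' while intracellular labels bleach.
#'
#' @param series an [image_stack] with \code{t} last.
#' @param compartment_masks named list of logical masks congruent with one
#'   frame (nonempty).
#' @param fit fit an exponential decay rate per compartment.
#' @param fit_floor fraction of the initial intensity below which frames
#'   are excluded from the fit (default 0.1); near the detector noise
#'   floor the compartment mean no longer decays exponentially.
#' @return list: \code{curves} (data.frame \code{frame, t_s, compartment,
#'   normalized_intensity}), \code{rates_per_frame} (named vector, if
#'   \code{fit}).
#' @export
bleaching_kinetics <- function(series, compartment_masks, fit = TRUE,
                               fit_floor = 0.1) {
  ti <- axis_index(series, "t")
  d <- dim(series$data)
  if (ti != length(d)) stop("t must be the last axis")
  if (d[ti] < 2L) stop("need at least 2 frames")
  m <- matrix(series$data * 1.0, prod(d[-ti]), d[ti])
  dt <- series$frame_interval_s %||% 1
  curves <- list()
  rates <- numeric(0)
  for (nm in names(compartment_masks)) {
    idx <- which(as.logical(compartment_masks[[nm]]))
    if (!length(idx)) stop("empty compartment mask: ", nm)
    mu <- colMeans(m[idx, , drop = FALSE])
    y <- mu / mu[1]
    curves[[nm]] <- data.frame(frame = seq_along(y) - 1L,
                               t_s = (seq_along(y) - 1L) * dt,
                               compartment = nm, normalized_intensity = y)
    if (fit) {
      use <- y >= fit_floor
      fitc <- lm(log(y[use]) ~ I(seq_along(y)[use] - 1L))
      rates[nm] <- 1 - exp(unname(coef(fitc)[2]))
    }
  }
  out <- list(curves = do.call(rbind, curves))
  if (fit) out$rates_per_frame <- rates
  out
}
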