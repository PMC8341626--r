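#' Temporal average of a time series
#'
#' Per-pixel arithmetic mean over the \code{t} axis. The averaged vascular
#' image shows the stable plasma-filled lumen of each vessel even while
#' dark cells flow through it, and is the standard input for vessel
#' segmentation before digital line scanning.
#'
#' @param series an [image_stack] whose last axis is \code{t}.
#' @return An [image_stack] of one rank lower (numeric data). A
#'   single-frame series is returned unchanged with a warning.
#' @export
temporal_average <- function(series) {
  ti <- axis_index(series, "t")
  d <- dim(series$data)
  if (ti != length(d)) stop("t must be the last axis")
  if (d[ti] < 2L) {
    warning("single frame; nothing to average")
    return(series)
  }
  avg <- collapse_time(series$data, rowMeans)
  image_stack(avg, series$axes[-ti],
              voxel_size_um = series$voxel_size_um,
              bit_depth = series$bit_depth)
}

#' Segment the vascular network
#'
#' Global threshold segmentation of the (smoothed) vessel image: vessels are
#' the brightest, most stable structure in a temporally averaged
#' negative-contrast series. Components smaller than \code{min_size_voxels}
#' are removed and enclosed holes (dark flowing cells frozen by averaging)
#' are filled slice-wise.
#'
#' @param image an [image_stack] (2D or 3D), vessels brighter than their
#'   surroundings; for a darker-lumen regime invert first.
#' @param method \code{"threshold"} (global Otsu, default) or
#'   \code{"fixed"} with \code{threshold} supplied in \code{params}.
#' @param params list: \code{smooth_sigma_um} (default 1), \code{threshold}
#'   (for \code{method = "fixed"}), \code{min_size_voxels} (default 50),
#'   \code{close_radius_px} (morphological closing radius applied slice-wise
#'   before hole filling, default 3; bridges occlusions up to about one
#'   flowing-cell radius left by dark cells resting against the lumen wall).
#' @return Logical array vessel mask, with attribute \code{"empty"} set to
#'   \code{TRUE} when nothing survives cleanup.
#' @export
segment_vessels <- function(image, method = c("threshold", "fixed"),
                            params = list()) {
  method <- match.arg(method)
  a <- if (inherits(image, "image_stack")) image$data * 1.0 else image * 1.0
  sp <- if (inherits(image, "image_stack")) axis_spacing(image) else
    rep(1, length(dim(a)))
  sigma_um <- params$smooth_sigma_um %||% 1
  min_size <- params$min_size_voxels %||% 50
  sm <- smooth_gaussian(a, ifelse(is.na(sp), 0, sigma_um / sp))
  thr <- if (method == "fixed") params$threshold else otsu_threshold(sm)
  mask <- sm > thr
  lab <- label_components(mask)
  keep <- which(tabulate(lab[lab > 0]) >= min_size)
  mask <- array(lab %in% keep, dim(mask))
  cr <- params$close_radius_px %||% 3
  if (cr > 0) mask <- close_slicewise(mask, cr)
  mask <- fill_holes_slicewise(mask)
  if (!any(mask)) attr(mask, "empty") <- TRUE
  mask
}

# Morphological closing with a disc brush, slice-wise for 3D input.
close_slicewise <- function(mask, radius_px) {
  brush <- EBImage::makeBrush(2 * radius_px + 1, "disc")
  cl <- function(m) EBImage::closing(EBImage::Image(m * 1), brush) > 0.5
  d <- dim(mask)
  if (length(d) == 2L) return(cl(mask))
  for (k in seq_len(d[3])) mask[, , k] <- cl(mask[, , k])
  mask
}

# Fill holes (background components not connected to the image border),
# slice-wise for 3D input.
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  fill2d <- function(m) {
    inv <- !m
    lab <- cpp_label(inv, as.integer(dim(m)), FALSE)
    border <- unique(c(lab[1, ], lab[nrow(m), ], lab[, 1], lab[, ncol(m)]))
    border <- border[border > 0]
    m | (lab > 0 & !(lab %in% border))
  }
  if (length(d) == 2L) return(fill2d(mask))
  for (k in seq_len(d[3])) mask[, , k] <- fill2d(mask[, , k])
  mask
}

#' Skeletonize a binary vessel mask
#'
#' Topology-preserving 2D thinning (Zhang-Suen): the skeleton is a subset of
#' the mask, one pixel wide, with the same number of 8-connected components.
#'
#' @param mask logical 2D matrix (nonempty).
#' @return Logical matrix skeleton.
#' @export
skeletonize_network <- function(mask) {
  if (length(dim(mask)) != 2L)
    stop("skeletonization operates on 2D masks (per-plane)")
  if (!any(mask)) stop("empty mask")
  m <- mask
  pad <- function(m) {
    out <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
    out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    out
  }
  p <- pad(m)
  nr <- nrow(p); nc <- ncol(p)
  sh <- function(a, dr, dc) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    a[ri, ci]
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors P2..P9 clockwise from north
      p2 <- sh(p, -1, 0); p3 <- sh(p, -1, 1); p4 <- sh(p, 0, 1)
      p5 <- sh(p, 1, 1); p6 <- sh(p, 1, 0); p7 <- sh(p, 1, -1)
      p8 <- sh(p, 0, -1); p9 <- sh(p, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqn <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nr, nc)
      for (i in 1:8) A <- A + (!seqn[[i]] & seqn[[i + 1]])
      if (sub == 1) {
        cond <- p & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- p & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { p[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]
}

#' Select straight vessel segments from a skeleton by Hough transform
#'
#' Accumulates skeleton pixels into a (angle, offset) Hough space (default
#' bins 1 degree x 1 px), then accepts peaks greedily in descending vote
#' order, suppressing lines whose snapped pixel support overlaps an accepted
#' segment by more than \code{overlap_frac}. Each accepted line is snapped
#' back to the skeleton pixels within \code{snap_tol_px} of it; the longest
#' contiguous run (arc gaps \eqn{\le} \code{gap_tol_px}) forms the segment
#' polyline, oriented by increasing arc position. Ties in the vote order are
#' broken by (angle, offset) lexicographic order, so the result is
#' deterministic.
#'
#' @param skeleton logical 2D matrix (e.g. from [skeletonize_network()]).
#' @param voxel_size_um named \code{c(x=, y=)} pixel size (um).
#' @param min_length_um minimum segment length (um).
#' @param max_segments maximum number of segments to return.
#' @param hough_params list: \code{angle_step_deg} (1), \code{rho_step_px}
#'   (1), \code{overlap_frac} (0.5), \code{snap_tol_px} (1.5),
#'   \code{gap_tol_px} (3).
#' @param vessel_mask optional mask used to attach a mean radius (um) to
#'   each segment via the distance transform.
#' @return List of \code{vessel_segment} objects: each has \code{id},
#'   \code{polyline} (n x 2 matrix of (x, y) um, voxel centers),
#'   \code{polyline_px} (row/col indices), \code{length_um},
#'   \code{angle_deg}, \code{mean_radius_um}.
#' @export
select_vessel_segments <- function(skeleton, voxel_size_um = c(x = 1, y = 1),
                                   min_length_um = 20, max_segments = 50,
                                   hough_params = list(),
                                   vessel_mask = NULL) {
  stopifnot(length(dim(skeleton)) == 2L, min_length_um > 0)
  astep <- hough_params$angle_step_deg %||% 1
  rstep <- hough_params$rho_step_px %||% 1
  ofrac <- hough_params$overlap_frac %||% 0.5
  snap <- hough_params$snap_tol_px %||% 1.5
  gap <- hough_params$gap_tol_px %||% 3
  px <- which(skeleton, arr.ind = TRUE) # (row, col)
  if (!nrow(px)) return(list())
  y <- px[, 1]; x <- px[, 2]
  thetas <- seq(0, 180 - astep, by = astep) * pi / 180
  rho <- outer(x, cos(thetas)) + outer(y, sin(thetas)) # n x ntheta
  rbin <- round(rho / rstep)
  rmin <- min(rbin)
  acc <- matrix(0L, max(rbin) - rmin + 1L, length(thetas))
  for (j in seq_along(thetas)) {
    tb <- tabulate(rbin[, j] - rmin + 1L, nbins = nrow(acc))
    acc[, j] <- tb
  }
  radius_map <- if (!is.null(vessel_mask))
    sqrt(cpp_edt_sq(!vessel_mask, as.integer(dim(vessel_mask)),
                    as.numeric(voxel_size_um[c("y", "x")]))) else NULL
  # candidate peaks ordered by votes desc, then (angle, offset)
  ord <- order(-acc, rep(seq_along(thetas), each = nrow(acc)),
               rep(seq_len(nrow(acc)), length(thetas)))
  min_votes <- max(3, floor(min_length_um / max(voxel_size_um)))
  segs <- list()
  used <- rep(FALSE, nrow(px))
  for (o in ord) {
    if (length(segs) >= max_segments) break
    v <- acc[o]
    if (v < min_votes) break
    j <- (o - 1L) %/% nrow(acc) + 1L
    rb <- (o - 1L) %% nrow(acc) + 1L
    th <- thetas[j]
    rho0 <- (rb + rmin - 1L) * rstep
    near <- which(abs(x * cos(th) + y * sin(th) - rho0) <= snap)
    if (length(near) < min_votes) next
    if (mean(used[near]) > ofrac) next
    # arc coordinate along the line
    tpos <- -x[near] * sin(th) + y[near] * cos(th)
    os <- order(tpos)
    near <- near[os]; tpos <- tpos[os]
    # longest run with gaps <= gap
    brk <- c(0, which(diff(tpos) > gap), length(tpos))
    runs <- cbind(head(brk, -1) + 1, tail(brk, -1))
    lens <- runs[, 2] - runs[, 1] + 1
    bi <- which.max(lens)
    sel <- near[runs[bi, 1]:runs[bi, 2]]
    if (length(sel) < 2) next
    poly_px <- cbind(row = y[sel], col = x[sel])
    # the segment geometry is the ideal straight line between the extreme
    # projections of the supporting pixels (a zigzagging pixel chain would
    # inflate the arc length and bias line-scan speeds)
    tsel <- range(tpos[runs[bi, 1]:runs[bi, 2]])
    ends_px <- cbind(x = cos(th) * rho0 - sin(th) * tsel,
                     y = sin(th) * rho0 + cos(th) * tsel)
    poly_um <- cbind(x = index_to_um(ends_px[, "x"], voxel_size_um["x"]),
                     y = index_to_um(ends_px[, "y"], voxel_size_um["y"]))
    len_um <- sum(sqrt(rowSums(diff(poly_um)^2)))
    if (len_um < min_length_um) next
    if (mean(used[sel]) > ofrac) next
    used[near] <- TRUE # retire the full collinear support
    mr <- if (!is.null(radius_map)) mean(radius_map[poly_px]) else NA_real_
    segs[[length(segs) + 1L]] <- structure(
      list(id = length(segs) + 1L, polyline = poly_um,
           polyline_px = poly_px, length_um = len_um,
           angle_deg = th * 180 / pi, mean_radius_um = mr),
      class = "vessel_segment")
  }
  segs
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("vessel_segment %d: %.1f um, %d px, angle %.1f deg\n",
              x$id, x$length_um, nrow(x$polyline), x$angle_deg))
  invisible(x)
}

#' Build a vessel network from a time series or static image
#'
#' Convenience pipeline: temporal average (if a \code{t} axis is present),
#' [segment_vessels()], [skeletonize_network()],
#' [select_vessel_segments()].
#'
#' @param image an [image_stack], 2D or 2D+t.
#' @param min_length_um minimum segment length.
#' @param params list passed through to the stages (see
#'   [segment_vessels()] and [select_vessel_segments()]).
#' @return Object of class \code{vessel_network}: list with \code{mask},
#'   \code{skeleton}, \code{segments}.
#' @export
build_vessel_network <- function(image, min_length_um = 20, params = list()) {
  img <- if (has_axis(image, "t")) temporal_average(image) else image
  mask <- segment_vessels(img, params = params)
  if (isTRUE(attr(mask, "empty"))) {
    return(structure(list(mask = mask, skeleton = mask, segments = list()),
                     class = "vessel_network"))
  }
  skel <- skeletonize_network(mask)
  segs <- select_vessel_segments(
    skel, voxel_size_um = img$voxel_size_um[c("x", "y")],
    min_length_um = min_length_um,
    hough_params = params, vessel_mask = mask)
  structure(list(mask = mask, skeleton = skel, segments = segs),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("vessel_network:", sum(x$mask), "mask px,", sum(x$skeleton),
      "skeleton px,", length(x$segments), "segments\n")
  invisible(x)
}
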