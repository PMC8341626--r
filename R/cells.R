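# Marker-controlled watershed detection of dark cells and the census
# statistics built on it.

# h-minima transform via grayscale reconstruction by dilation on the negated
# image: fills all minima shallower than h.
hminima_transform <- function(img, h) {
  d <- dim(img)
  neg <- -img
  rec <- cpp_reconstruct_dilate(as.numeric(neg - h), as.numeric(neg),
                                as.integer(d), TRUE)
  out <- -rec
  dim(out) <- d
  out
}

# Markers = connected regional minima (depth >= h) of the smoothed image,
# restricted to the foreground mask.
find_markers <- function(smoothed, h, foreground) {
  d <- dim(smoothed)
  hm <- hminima_transform(smoothed, h)
  mins <- cpp_regional_minima(as.numeric(hm), as.integer(d),
                              as.logical(foreground), TRUE)
  mins <- mins & foreground
  cpp_label(mins, as.integer(d), TRUE)
}

watershed_labels <- function(smoothed, markers, foreground) {
  d <- dim(smoothed)
  cpp_watershed(as.numeric(smoothed), as.integer(markers),
                as.logical(foreground), as.integer(d), TRUE)
}

drop_labels <- function(labels, drop) {
  if (!length(drop)) return(labels)
  labels[labels %in% drop] <- 0L
  labels
}

relabel_sequential <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (!length(u)) return(labels)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  labels[labels > 0] <- map[labels[labels > 0]]
  labels
}

#' Detect dark cells in a 2D section by marker-controlled watershed
#'
#' Cells appear as dark objects against the bright dye-filled interstitium.
#' The slice is Gaussian-smoothed, the foreground is the sub-threshold
#' (dark) region, markers are the regional minima of the smoothed image with
#' depth at least \code{h} (h-minima), and watershed flooding grows each
#' marker over the foreground with deterministic lexicographic tie-breaks.
#' Regions touching the exclusion mask are discarded, then size-filtered.
#'
#' @param slice_image an [image_stack] of rank 2, or a matrix (then
#'   \code{voxel_size_um} applies).
#' @param exclusion optional [exclusion_mask()] or logical matrix.
#' @param params list: \code{smooth_sigma_um} (default one x-pixel),
#'   \code{h_frac} (marker depth as a fraction of the smoothed dynamic
#'   range, default 0.1), \code{threshold} (foreground threshold, default
#'   Otsu), \code{min_diameter_um} (3), \code{max_diameter_um} (25),
#'   \code{polarity} (\code{"dark"} or \code{"bright"}; \code{"bright"}
#'   inverts internally so detection is equivariant to LUT inversion).
#' @param voxel_size_um pixel size when \code{slice_image} is a bare matrix.
#' @return Integer label matrix with attribute \code{"regions"}: a
#'   data.frame of per-region label, centroid (um), area (um^2 and px) and
#'   equivalent diameter (um).
#' @export
detect_cells_2d <- function(slice_image, exclusion = NULL, params = list(),
                            voxel_size_um = c(x = 1, y = 1)) {
  if (inherits(slice_image, "image_stack")) {
    a <- slice_image$data * 1.0
    voxel_size_um <- slice_image$voxel_size_um
  } else a <- slice_image * 1.0
  stopifnot(length(dim(a)) == 2L)
  vox <- voxel_size_um[c("y", "x")] # array order
  polarity <- params$polarity %||% "dark"
  if (polarity == "bright") a <- max(a) - a
  sigma_um <- params$smooth_sigma_um %||% unname(voxel_size_um["x"])
  sm <- smooth_gaussian(a, sigma_um / vox)
  rng <- diff(range(sm))
  h <- (params$h_frac %||% 0.1) * rng
  thr <- params$threshold %||% otsu_threshold(sm)
  excl <- if (is.null(exclusion)) array(FALSE, dim(a)) else
    (if (inherits(exclusion, "exclusion_mask")) exclusion$mask else exclusion)
  foreground <- (sm < thr) & !excl
  if (!any(foreground)) {
    lab <- array(0L, dim(a))
    attr(lab, "regions") <- empty_regions()
    return(lab)
  }
  markers <- find_markers(sm, h, foreground)
  lab <- watershed_labels(sm, markers, foreground)
  # discard regions touching exclusion (adjacent within 1 px)
  if (any(excl)) {
    grown <- excl
    grown[-1, ] <- grown[-1, ] | excl[-nrow(excl), ]
    grown[-nrow(excl), ] <- grown[-nrow(excl), ] | excl[-1, ]
    grown[, -1] <- grown[, -1] | excl[, -ncol(excl)]
    grown[, -ncol(excl)] <- grown[, -ncol(excl)] | excl[, -1]
    lab <- drop_labels(lab, unique(lab[grown & lab > 0]))
  }
  px_area <- prod(vox)
  min_a <- pi * ((params$min_diameter_um %||% 3) / 2)^2
  max_a <- pi * ((params$max_diameter_um %||% 25) / 2)^2
  cnt <- tabulate(lab[lab > 0])
  bad <- which(cnt * px_area < min_a | cnt * px_area > max_a)
  lab <- relabel_sequential(drop_labels(lab, bad))
  attr(lab, "regions") <- region_table_2d(lab, vox)
  lab
}

empty_regions <- function() {
  data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
             area_px = integer(0), area_um2 = numeric(0),
             equivalent_diameter_um = numeric(0))
}

region_table_2d <- function(lab, vox_yx) {
  idx <- which(lab > 0)
  if (!length(idx)) return(empty_regions())
  l <- lab[idx]
  rc <- arrayInd(idx, dim(lab))
  area <- tabulate(l)
  labs <- which(area > 0)
  ys <- vapply(split(rc[, 1], l), mean, numeric(1))
  xs <- vapply(split(rc[, 2], l), mean, numeric(1))
  data.frame(label = labs,
             x_um = index_to_um(unname(xs), vox_yx["x"]),
             y_um = index_to_um(unname(ys), vox_yx["y"]),
             area_px = area[labs],
             area_um2 = area[labs] * prod(vox_yx),
             equivalent_diameter_um =
               2 * sqrt(area[labs] * prod(vox_yx) / pi))
}

#' Link 2D detections across z into 3D cell records (sphere-packing model)
#'
#' Marrow cells are modeled as roughly spherical, so a cell appears as a
#' stack of roughly concentric 2D regions in consecutive sections. Regions
#' are linked across z by centroid proximity (within \code{link_radius_um})
#' and area continuity (equivalent-radius ratio at least
#' \code{area_ratio_min}); each track becomes one cell whose z centroid is
#' the area-weighted mean slice position and whose equivalent diameter is
#' that of the sphere consistent with the maximal cross-section,
#' \code{d = 2 sqrt(A_max / pi)}.
#'
#' @param per_slice_labels list of label matrices (one per z slice), each
#'   carrying the \code{"regions"} attribute from [detect_cells_2d()].
#' @param voxel_size_um named \code{c(x=, y=, z=)} voxel sizes.
#' @param params list: \code{link_radius_um} (default 0.6 x median 2D
#'   equivalent radius), \code{area_ratio_min} (0.1), \code{min_slices}
#'   (2: unlinked single-slice regions are kept only if their area exceeds
#'   \code{single_slice_min_area_um2}, default the area of a 4 um circle).
#' @param source_stack optional [image_stack] to attach per-cell mean
#'   intensities.
#' @return data.frame of cell records: centroid (um), equivalent diameter
#'   (um), maximal area, slice span, mean intensity (if a source stack is
#'   given).
#' @export
build_3d_packing <- function(per_slice_labels, voxel_size_um,
                             params = list(), source_stack = NULL) {
  regions <- lapply(per_slice_labels, attr, "regions")
  nz <- length(regions)
  dz <- unname(voxel_size_um["z"])
  all_r <- unlist(lapply(regions, function(r) r$equivalent_diameter_um / 2))
  if (!length(all_r))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), equivalent_diameter_um = numeric(0),
                      max_area_um2 = numeric(0), n_slices = integer(0)))
  link_r <- params$link_radius_um %||% (0.6 * median(all_r))
  ratio_min <- params$area_ratio_min %||% 0.1
  ss_min_area <- params$single_slice_min_area_um2 %||% (pi * 2^2)

  # active tracks: list(idx = track id), track data accumulated in lists
  tracks <- list() # each: list(xs, ys, zs(slice), areas, last_slice, last_x, last_y, last_area)
  active <- integer(0)
  for (k in seq_len(nz)) {
    reg <- regions[[k]]
    if (is.null(reg) || !nrow(reg)) { active <- integer(0); next }
    prev <- active
    active <- integer(0)
    taken <- rep(FALSE, nrow(reg))
    if (length(prev)) {
      # greedy nearest matching, deterministic by distance then track id
      cand <- expand.grid(ti = prev, ri = seq_len(nrow(reg)))
      cand$d <- sqrt((vapply(tracks[cand$ti], function(t) t$last_x, numeric(1)) -
                        reg$x_um[cand$ri])^2 +
                     (vapply(tracks[cand$ti], function(t) t$last_y, numeric(1)) -
                        reg$y_um[cand$ri])^2)
      la <- vapply(tracks[cand$ti], function(t) t$last_area, numeric(1))
      ra <- reg$area_um2[cand$ri]
      cand$ok <- cand$d <= link_r &
        sqrt(pmin(la, ra) / pmax(la, ra)) >= ratio_min
      cand <- cand[cand$ok, , drop = FALSE]
      cand <- cand[order(cand$d, cand$ti, cand$ri), , drop = FALSE]
      used_t <- logical(length(tracks))
      for (i in seq_len(nrow(cand))) {
        ti <- cand$ti[i]; ri <- cand$ri[i]
        if (used_t[ti] || taken[ri]) next
        used_t[ti] <- TRUE; taken[ri] <- TRUE
        t <- tracks[[ti]]
        t$xs <- c(t$xs, reg$x_um[ri]); t$ys <- c(t$ys, reg$y_um[ri])
        t$zs <- c(t$zs, k); t$areas <- c(t$areas, reg$area_um2[ri])
        t$last_x <- reg$x_um[ri]; t$last_y <- reg$y_um[ri]
        t$last_area <- reg$area_um2[ri]
        t$labels <- c(t$labels, reg$label[ri]); t$slices <- c(t$slices, k)
        tracks[[ti]] <- t
        active <- c(active, ti)
      }
    }
    for (ri in which(!taken)) {
      tracks[[length(tracks) + 1L]] <- list(
        xs = reg$x_um[ri], ys = reg$y_um[ri], zs = k,
        areas = reg$area_um2[ri],
        last_x = reg$x_um[ri], last_y = reg$y_um[ri],
        last_area = reg$area_um2[ri],
        labels = reg$label[ri], slices = k)
      active <- c(active, length(tracks))
    }
  }
  keep <- vapply(tracks, function(t)
    length(t$zs) >= (params$min_slices %||% 2L) ||
      max(t$areas) >= ss_min_area, logical(1))
  tracks <- tracks[keep]
  if (!length(tracks))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), equivalent_diameter_um = numeric(0),
                      max_area_um2 = numeric(0), n_slices = integer(0)))
  rec <- do.call(rbind, lapply(tracks, function(t) {
    wt <- t$areas / sum(t$areas)
    data.frame(x_um = sum(t$xs * wt), y_um = sum(t$ys * wt),
               z_um = index_to_um(sum(t$zs * wt), dz),
               equivalent_diameter_um = 2 * sqrt(max(t$areas) / pi),
               max_area_um2 = max(t$areas),
               n_slices = length(t$zs))
  }))
  if (!is.null(source_stack)) {
    rec$mean_intensity <- vapply(tracks, function(t) {
      vals <- unlist(lapply(seq_along(t$slices), function(i) {
        lab <- per_slice_labels[[t$slices[i]]]
        source_stack$data[, , t$slices[i]][lab == t$labels[i]]
      }))
      mean(vals)
    }, numeric(1))
  }
  rec
}

#' Detect cells by 2D watershed per slice plus 3D packing
#'
#' Runs [detect_cells_2d()] on every z section and joins the sections with
#' [build_3d_packing()].
#'
#' @param stack a 3D [image_stack] with axes \code{yxz}.
#' @param exclusion optional [exclusion_mask()] (3D).
#' @param params passed to both stages.
#' @return data.frame of 3D cell records.
#' @export
detect_cells_stackwise <- function(stack, exclusion = NULL, params = list()) {
  d <- dim(stack$data)
  excl <- if (is.null(exclusion)) NULL else
    (if (inherits(exclusion, "exclusion_mask")) exclusion$mask else exclusion)
  labs <- lapply(seq_len(d[3]), function(k) {
    detect_cells_2d(stack$data[, , k],
                    exclusion = if (is.null(excl)) NULL else excl[, , k],
                    params = params,
                    voxel_size_um = stack$voxel_size_um)
  })
  build_3d_packing(labs, stack$voxel_size_um, params = params,
                   source_stack = stack)
}

#' Direct 3D marker-controlled watershed cell segmentation
#'
#' Anisotropy-aware 3D analogue of [detect_cells_2d()]: smoothing uses a
#' physical sigma (um) converted to per-axis voxel units, markers are 3D
#' h-minima, and flooding runs in 26-connectivity over the dark foreground.
#' The equivalent diameter comes from the labeled volume,
#' \code{d = 2 (3 V / 4 pi)^(1/3)}.
#'
#' @param stack a 3D [image_stack] (axes \code{yxz}).
#' @param exclusion optional [exclusion_mask()].
#' @param params as in [detect_cells_2d()]; size filters act on volume via
#'   the sphere equivalent of \code{min/max_diameter_um}.
#' @return list with \code{labels} (integer 3D array) and \code{cells}
#'   (data.frame: centroid um, equivalent diameter um, volume, mean
#'   intensity).
#' @export
segment_cells_3d <- function(stack, exclusion = NULL, params = list()) {
  a <- stack$data * 1.0
  d <- dim(a)
  stopifnot(length(d) == 3L)
  vox <- stack$voxel_size_um[c("y", "x", "z")]
  polarity <- params$polarity %||% "dark"
  if (polarity == "bright") a <- max(a) - a
  sigma_um <- params$smooth_sigma_um %||% unname(stack$voxel_size_um["x"])
  sm <- smooth_gaussian(a, sigma_um / vox)
  h <- (params$h_frac %||% 0.1) * diff(range(sm))
  thr <- params$threshold %||% otsu_threshold(sm)
  excl <- if (is.null(exclusion)) array(FALSE, d) else
    (if (inherits(exclusion, "exclusion_mask")) exclusion$mask else exclusion)
  foreground <- (sm < thr) & !excl
  if (!any(foreground)) {
    return(list(labels = array(0L, d), cells = empty_cells_3d()))
  }
  markers <- find_markers(sm, h, foreground)
  lab <- watershed_labels(sm, markers, foreground)
  if (any(excl)) {
    touching <- unique(lab[grow_mask(excl) & lab > 0])
    lab <- drop_labels(lab, touching)
  }
  vx <- prod(vox)
  min_v <- 4 / 3 * pi * ((params$min_diameter_um %||% 3) / 2)^3
  max_v <- 4 / 3 * pi * ((params$max_diameter_um %||% 25) / 2)^3
  cnt <- tabulate(lab[lab > 0])
  bad <- which(cnt * vx < min_v | cnt * vx > max_v)
  lab <- relabel_sequential(drop_labels(lab, bad))
  idx <- which(lab > 0)
  if (!length(idx)) return(list(labels = lab, cells = empty_cells_3d()))
  l <- lab[idx]
  co <- arrayInd(idx, d)
  vol <- tabulate(l)
  labs <- which(vol > 0)
  ys <- vapply(split(co[, 1], l), mean, numeric(1))
  xs <- vapply(split(co[, 2], l), mean, numeric(1))
  zs <- vapply(split(co[, 3], l), mean, numeric(1))
  mi <- vapply(split(stack$data[idx], l), mean, numeric(1))
  cells <- data.frame(
    x_um = index_to_um(unname(xs), vox["x"]),
    y_um = index_to_um(unname(ys), vox["y"]),
    z_um = index_to_um(unname(zs), vox["z"]),
    volume_um3 = vol[labs] * vx,
    equivalent_diameter_um = 2 * (3 * vol[labs] * vx / (4 * pi))^(1 / 3),
    mean_intensity = unname(mi),
    label = labs)
  list(labels = lab, cells = cells)
}

empty_cells_3d <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             volume_um3 = numeric(0), equivalent_diameter_um = numeric(0),
             mean_intensity = numeric(0), label = integer(0))
}

grow_mask <- function(m) {
  d <- dim(m)
  out <- m
  for (ax in seq_along(d)) {
    if (d[ax] == 1) next
    perm <- c(ax, setdiff(seq_along(d), ax))
    mm <- aperm(out, perm)
    dm <- dim(mm)
    dim(mm) <- c(d[ax], prod(d[-ax]))
    mm <- mm | shift_rows(mm, 1L) | shift_rows(mm, -1L)
    dim(mm) <- dm
    out <- aperm(mm, order(perm))
  }
  out
}

#' Cell density
#'
#' Number of cells per unit volume, also expressed per the standard
#' 100 x 100 x 20 um^3 analysis ROI.
#'
#' @param cells data.frame of cell records (or an integer count).
#' @param roi_volume_um3 ROI volume in um^3 (> 0).
#' @return list: \code{density_cells_per_um3},
#'   \code{cells_per_standard_roi} (100 x 100 x 20 um^3), \code{count}.
#' @export
cell_density <- function(cells, roi_volume_um3) {
  if (roi_volume_um3 <= 0) stop("ROI volume must be positive")
  n <- if (is.data.frame(cells)) nrow(cells) else as.integer(cells)
  list(density_cells_per_um3 = n / roi_volume_um3,
       cells_per_standard_roi = n / roi_volume_um3 * (100 * 100 * 20),
       count = n)
}

#' Fraction of cells below a diameter threshold
#'
#' Small-cell fraction of a census; the sub-10-um bin tracks
#' neutrophil-sized cells, which egress from the marrow under inflammatory
#' stimulation.
#'
#' @param cells data.frame with \code{equivalent_diameter_um} (or
#'   \code{diameter_um}).
#' @param threshold_um diameter threshold (default 10).
#' @return list: \code{fraction}, \code{count}, \code{n}.
#' @export
diameter_fraction_below <- function(cells, threshold_um = 10) {
  d <- cells$equivalent_diameter_um %||% cells$diameter_um
  if (is.null(d) || !length(d)) stop("empty census: fraction undefined")
  list(fraction = mean(d < threshold_um), count = sum(d < threshold_um),
       n = length(d))
}

#' Per-label mean intensity
#'
#' For each label, the sum of source intensities over its pixels divided by
#' the pixel count.
#'
#' @param labels integer label array.
#' @param source_image congruent intensity array or [image_stack].
#' @return data.frame \code{label, mean_intensity, n_px}.
#' @export
per_cell_intensity <- function(labels, source_image) {
  a <- if (inherits(source_image, "image_stack")) source_image$data else source_image
  if (!identical(dim(a), dim(labels))) stop("labels/image shape mismatch")
  idx <- which(labels > 0)
  if (!length(idx))
    return(data.frame(label = integer(0), mean_intensity = numeric(0),
                      n_px = integer(0)))
  l <- labels[idx]
  mi <- vapply(split(a[idx] * 1.0, l), mean, numeric(1))
  n <- tabulate(l)
  labs <- which(n > 0)
  data.frame(label = labs, mean_intensity = unname(mi), n_px = n[labs])
}

#' Build a cell census
#'
#' @param cells data.frame of cell records.
#' @param roi_volume_um3 ROI volume (um^3).
#' @param bin_width_um diameter histogram bin width (default 2 um).
#' @return Object of class \code{cell_census}: cells, ROI volume, density,
#'   diameter histogram (breaks + counts).
#' @export
cell_census <- function(cells, roi_volume_um3, bin_width_um = 2) {
  d <- cells$equivalent_diameter_um %||% cells$diameter_um %||% numeric(0)
  upper <- max(c(d, 0)) + bin_width_um
  breaks <- seq(0, ceiling(upper / bin_width_um) * bin_width_um,
                by = bin_width_um)
  counts <- if (length(d)) hist(d, breaks = breaks, plot = FALSE)$counts
    else integer(length(breaks) - 1L)
  structure(list(cells = cells, roi_volume_um3 = roi_volume_um3,
                 density = cell_density(cells, roi_volume_um3),
                 diameter_histogram = list(breaks_um = breaks,
                                           counts = counts)),
            class = "cell_census")
}

#' @export
print.cell_census <- function(x, ...) {
  cat("cell_census:", nrow(x$cells), "cells in", x$roi_volume_um3,
      "um^3 =>", signif(x$density$cells_per_standard_roi, 4),
      "cells per 100x100x20 um^3 ROI\n")
  invisible(x)
}
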