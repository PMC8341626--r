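# Distance-to-vessel statistics and random-dot reference distributions.

#' Anisotropic Euclidean distance transform
#'
#' Distance (um) from every voxel center to the nearest \code{TRUE} voxel
#' center of \code{feature}, honoring per-axis voxel sizes. Exact separable
#' transform (parabolic lower envelopes).
#'
#' @param feature logical array.
#' @param spacing_um numeric spacing per array dimension (um).
#' @return Numeric array of distances; \code{Inf} if \code{feature} is empty.
#' @export
distance_transform <- function(feature, spacing_um) {
  d <- dim(feature)
  stopifnot(length(spacing_um) == length(d))
  out <- sqrt(cpp_edt_sq(as.logical(feature), as.integer(d),
                         as.numeric(spacing_um)))
  array(out, d)
}

# Multilinear interpolation of an array at continuous 1-based indices
# (n x ndim matrix), clamped to the array domain.
interp_array <- function(a, idx) {
  d <- dim(a)
  nd <- length(d)
  idx <- matrix(idx, ncol = nd)
  idx <- pmin(pmax(idx, 1), matrix(d, nrow(idx), nd, byrow = TRUE))
  lo <- floor(idx)
  lo <- pmin(lo, matrix(pmax(d - 1L, 1L), nrow(idx), nd, byrow = TRUE))
  fr <- idx - lo
  out <- numeric(nrow(idx))
  for (corner in seq_len(2^nd) - 1L) {
    bits <- as.integer(intToBits(corner))[seq_len(nd)]
    ci <- lo + matrix(bits, nrow(idx), nd, byrow = TRUE)
    ci <- pmin(ci, matrix(d, nrow(idx), nd, byrow = TRUE))
    w <- rep(1, nrow(idx))
    for (ax in seq_len(nd))
      w <- w * ifelse(bits[ax] == 1, fr[, ax], 1 - fr[, ax])
    out <- out + w * a[ci]
  }
  out
}

#' Distance from cell centroids to the nearest blood-vessel wall
#'
#' Computes the anisotropy-aware Euclidean distance transform of the vessel
#' mask's complement and samples it at the centroid positions by
#' multilinear interpolation. The "wall" is the surface of the binary
#' vessel mask: distances are zero for centroids inside the mask.
#'
#' @param centroids_um n x 3 matrix or data.frame with columns
#'   \code{x_um, y_um, z_um} (2D input: \code{x_um, y_um}).
#' @param vessel_mask logical array in \code{yxz} (or \code{yx}) order;
#'   must be nonempty.
#' @param voxel_size_um named voxel sizes (um).
#' @return Numeric vector of distances (um).
#' @export
distance_to_vessel <- function(centroids_um, vessel_mask, voxel_size_um) {
  if (!any(vessel_mask)) stop("empty vessel mask: distances undefined")
  d <- dim(vessel_mask)
  nd <- length(d)
  sp <- if (nd == 3) voxel_size_um[c("y", "x", "z")] else
    voxel_size_um[c("y", "x")]
  dt <- distance_transform(vessel_mask, sp)
  cm <- as.data.frame(centroids_um)
  cols <- if (nd == 3) c("y_um", "x_um", "z_um") else c("y_um", "x_um")
  if (!all(cols %in% names(cm))) {
    cm <- as.matrix(centroids_um)
    # assume (x, y[, z]) column order
    cm <- if (nd == 3) data.frame(y_um = cm[, 2], x_um = cm[, 1],
                                  z_um = cm[, 3]) else
      data.frame(y_um = cm[, 2], x_um = cm[, 1])
  }
  idx <- sapply(seq_len(nd), function(ax)
    um_to_index(cm[[cols[ax]]], sp[ax]))
  idx <- matrix(idx, ncol = nd)
  out <- interp_array(dt, idx)
  # centroids whose containing voxel is inside the mask are at distance 0
  near <- pmin(pmax(round(idx), 1), matrix(d, nrow(idx), nd, byrow = TRUE))
  inside <- vessel_mask[near]
  out[inside] <- 0
  out
}

#' Fraction of distances within a threshold
#'
#' @param distances nonempty numeric vector (um).
#' @param threshold_um threshold (um), e.g. 30.
#' @return Proportion of distances \code{<= threshold_um}.
#' @export
fraction_within <- function(distances, threshold_um) {
  if (!length(distances)) stop("empty distance set")
  mean(distances <= threshold_um)
}

#' Distance histogram and summary
#'
#' @param distances numeric vector (um).
#' @param bin_width_um histogram bin width (default 5 um).
#' @param thresholds_um thresholds at which to report cumulative fractions.
#' @return Object of class \code{distance_result}: distances, histogram,
#'   cumulative fractions.
#' @export
distance_result <- function(distances, bin_width_um = 5,
                            thresholds_um = 30) {
  breaks <- seq(0, ceiling(max(c(distances, bin_width_um)) / bin_width_um) *
                  bin_width_um, by = bin_width_um)
  h <- hist(distances, breaks = breaks, plot = FALSE)
  fr <- vapply(thresholds_um, function(t) fraction_within(distances, t),
               numeric(1))
  structure(list(distances_um = distances,
                 histogram = list(breaks_um = breaks, counts = h$counts),
                 fraction_within = setNames(fr, paste0(thresholds_um, "um"))),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat("distance_result:", length(x$distances_um), "cells; median",
      signif(median(x$distances_um), 4), "um;",
      paste(sprintf("%.1f%% within %s", 100 * x$fraction_within,
                    names(x$fraction_within)), collapse = ", "), "\n")
  invisible(x)
}

#' Uniform random reference positions within an ROI
#'
#' Places \code{n} uniformly distributed reference points inside the ROI
#' mask (vessels/bone already excluded from the mask by the caller),
#' reproducibly per seed: the spatially uniform null against which a
#' labeled population's vessel-distance distribution is contrasted.
#'
#' @param n number of dots (\code{n <= sum(roi_mask)}).
#' @param roi_mask logical array (\code{yx} or \code{yxz} order).
#' @param voxel_size_um named voxel sizes (um).
#' @param seed integer seed.
#' @return data.frame of positions (\code{x_um, y_um[, z_um]}), jittered
#'   uniformly within their voxels.
#' @export
random_dot_reference <- function(n, roi_mask, voxel_size_um, seed = 1) {
  avail <- which(roi_mask)
  if (n > length(avail)) stop("n exceeds the number of available voxels")
  d <- dim(roi_mask)
  nd <- length(d)
  sp <- if (nd == 3) voxel_size_um[c("y", "x", "z")] else
    voxel_size_um[c("y", "x")]
  with_seed(seed, {
    pick <- if (n > 0) sample(avail, n) else integer(0)
    co <- arrayInd(pick, d)
    jit <- matrix(runif(n * nd, -0.5, 0.5), n, nd)
    # voxel-center convention: center of voxel i is (i - 0.5) * spacing
    pos <- sweep(co - 0.5 + jit, 2, sp, `*`)
    out <- data.frame(x_um = pos[, 2], y_um = pos[, 1])
    if (nd == 3) out$z_um <- pos[, 3]
    out
  })
}
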