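#' Invert the lookup table of a stack
#'
#' Negative-contrast images show unlabeled cells as dark objects on a bright
#' interstitium; inverting the LUT (\code{out = 2^bit_depth - 1 - in})
#' displays them as bright objects. The operation is an involution and
#' preserves calibration.
#'
#' @param stack an [image_stack] with integer data.
#' @param bit_depth bit depth to invert against; defaults to the stack's.
#' @return The inverted [image_stack].
#' @export
invert_lut <- function(stack, bit_depth = stack$bit_depth) {
  maxv <- 2^bit_depth - 1
  if (min(stack$data) < 0 || max(stack$data) > maxv)
    stop("intensities exceed the stated bit depth")
  was_int <- is.integer(stack$data)
  stack$data <- maxv - stack$data
  if (was_int) storage.mode(stack$data) <- "integer"
  stack
}

#' Percentile-based linear contrast enhancement
#'
#' Linearly rescales intensities so the \code{low_pct} and \code{high_pct}
#' percentiles map to the full bit-depth range, clipping outside. Monotone
#' among non-clipped values. A constant image is returned unchanged with a
#' warning.
#'
#' @param stack an [image_stack].
#' @param low_pct,high_pct percentiles in \code{[0, 100]},
#'   \code{low_pct < high_pct}; defaults 0.5 and 99.5.
#' @return The enhanced [image_stack] (integer data).
#' @export
enhance_contrast <- function(stack, low_pct = 0.5, high_pct = 99.5) {
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  q <- quantile(stack$data, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[1] == q[2]) {
    warning("constant intensity in the percentile window; image unchanged")
    return(stack)
  }
  maxv <- 2^stack$bit_depth - 1
  out <- (stack$data - q[1]) / (q[2] - q[1]) * maxv
  stack$data <- quantize(out, stack$bit_depth)
  stack
}

#' Estimate the background intensity floor
#'
#' Robust low-intensity floor used as the reference for low-signal
#' exclusion: the mode of the histogram of the lowest intensity decile
#' (integer data: exact mode; float data: 64-bin histogram mode). Robust to
#' isolated dark outliers, unlike the global minimum.
#'
#' @param stack an [image_stack] (or bare array).
#' @param exclusion optional [exclusion_mask()] or logical array; excluded
#'   voxels are ignored. At least 1\% of voxels must remain.
#' @return Scalar background intensity.
#' @export
estimate_background <- function(stack, exclusion = NULL) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  v <- as.vector(a)
  if (!is.null(exclusion)) {
    m <- if (inherits(exclusion, "exclusion_mask")) exclusion$mask else exclusion
    v <- v[!as.logical(m)]
    if (length(v) < 0.01 * length(a))
      stop("exclusion mask covers more than 99% of voxels")
  }
  lo <- v[v <= quantile(v, 0.1, names = FALSE)]
  if (length(unique(lo)) == 1L) return(lo[1])
  if (is.integer(a)) {
    tab <- tabulate(lo - min(lo) + 1L)
    return(min(lo) + which.max(tab) - 1L)
  }
  h <- hist(lo, breaks = 64, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Replace vessel signal by the background estimate
#'
#' Sets voxels inside \code{vessel_mask} to the background estimate (not
#' zero) so the array geometry stays intact for distance transforms, while
#' removing the bright vascular signal before cell segmentation. No voxel
#' outside the mask is modified.
#'
#' @param stack an [image_stack].
#' @param vessel_mask logical array congruent with the stack.
#' @param background replacement value; default [estimate_background()] of
#'   the non-vessel voxels.
#' @return The modified [image_stack].
#' @export
remove_vessel_signal <- function(stack, vessel_mask,
                                 background = NULL) {
  if (!identical(dim(vessel_mask), dim(stack$data)))
    stop("vessel mask shape mismatch")
  if (is.null(background))
    background <- estimate_background(stack, exclusion = vessel_mask)
  a <- stack$data
  a[as.logical(vessel_mask)] <-
    if (is.integer(a)) as.integer(round(background)) else background
  stack$data <- a
  stack
}

#' Exclusion mask
#'
#' Binary mask of voxels to exclude from cell detection, with provenance
#' labels from \code{{bone, vessel, low_signal}}.
#'
#' @param mask logical array.
#' @param provenance character vector of contributing criteria.
#' @return Object of class \code{exclusion_mask}.
#' @export
exclusion_mask <- function(mask, provenance = character(0)) {
  structure(list(mask = as.logical(mask) |> array(dim(mask)),
                 provenance = provenance),
            class = "exclusion_mask")
}

#' @export
print.exclusion_mask <- function(x, ...) {
  cat("exclusion_mask: ", sum(x$mask), "/", length(x$mask),
      " voxels excluded [", paste(x$provenance, collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Build an exclusion mask from bone, vessel and low-signal criteria
#'
#' Union of (i) a thresholded bone/SHG channel, (ii) a vessel mask, and
#' (iii) voxels below a low-signal threshold. With
#' \code{low_signal_threshold = "auto"} the threshold is
#' \code{factor * estimate_background(stack)}.
#'
#' @param stack the negative-contrast [image_stack].
#' @param bone_channel optional second-channel [image_stack] or array; bone
#'   voxels are those above its Otsu threshold.
#' @param vessel_mask optional logical array.
#' @param low_signal_threshold scalar intensity, \code{"auto"}, or
#'   \code{NULL} to skip.
#' @param factor multiplier for the automatic threshold (default 1.5).
#' @return An [exclusion_mask()]. If no criteria are supplied, an empty mask
#'   with a warning.
#' @export
build_exclusion_mask <- function(stack, bone_channel = NULL,
                                 vessel_mask = NULL,
                                 low_signal_threshold = NULL,
                                 factor = 1.5) {
  a <- stack$data
  m <- array(FALSE, dim(a))
  prov <- character(0)
  if (!is.null(bone_channel)) {
    b <- if (inherits(bone_channel, "image_stack")) bone_channel$data else bone_channel
    if (!identical(dim(b), dim(a))) stop("bone channel shape mismatch")
    m <- m | (b > otsu_threshold(b))
    prov <- c(prov, "bone")
  }
  if (!is.null(vessel_mask)) {
    if (!identical(dim(vessel_mask), dim(a))) stop("vessel mask shape mismatch")
    m <- m | as.logical(vessel_mask)
    prov <- c(prov, "vessel")
  }
  if (!is.null(low_signal_threshold)) {
    thr <- if (identical(low_signal_threshold, "auto"))
      factor * estimate_background(stack) else low_signal_threshold
    m <- m | (a < thr)
    prov <- c(prov, "low_signal")
  }
  if (!length(prov))
    warning("no exclusion criteria supplied; mask is empty")
  exclusion_mask(m, prov)
}
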