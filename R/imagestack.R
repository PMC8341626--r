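#' Calibrated image stack
#'
#' Container for single-channel intensity data with axis semantics and
#' physical calibration. The array rank equals the number of axis labels;
#' spatial axes are drawn from \code{x}, \code{y}, \code{z} and the time
#' axis is \code{t}. Physical coordinates follow the voxel-center
#' convention: the center of voxel \code{i} (1-based) lies at
#' \code{(i - 0.5) * voxel_size}.
#'
#' @param data numeric or integer array.
#' @param axes axis labels, either a character vector (one per array
#'   dimension) or a single string such as \code{"yxz"}.
#' @param voxel_size_um named numeric vector of voxel sizes in micrometers
#'   for the spatial axes present, e.g. \code{c(x = 0.5, y = 0.5, z = 0.34)}.
#' @param frame_interval_s seconds between frames; required when a \code{t}
#'   axis is present.
#' @param bit_depth source bit depth (8 or 16) for integer data.
#' @return An object of class \code{image_stack}: a list with elements
#'   \code{data}, \code{axes}, \code{voxel_size_um}, \code{frame_interval_s},
#'   \code{bit_depth}.
#' @examples
#' s <- image_stack(array(0L, c(8, 8, 4)), "yxz",
#'                  voxel_size_um = c(x = 0.5, y = 0.5, z = 0.34))
#' s
#' @export
image_stack <- function(data, axes, voxel_size_um = c(x = 1, y = 1, z = 1),
                        frame_interval_s = NULL, bit_depth = 8L) {
  if (is.character(axes) && length(axes) == 1L && nchar(axes) > 1L)
    axes <- strsplit(axes, "")[[1]]
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  if (length(axes) != length(d))
    stop("rank mismatch: ", length(axes), " axis labels for a rank-",
         length(d), " array")
  if (!all(axes %in% c("x", "y", "z", "t")) || anyDuplicated(axes))
    stop("axes must be distinct labels from {x, y, z, t}")
  sp <- setdiff(axes, "t")
  missing_cal <- setdiff(sp, names(voxel_size_um))
  if (length(missing_cal))
    stop("missing voxel size for axis: ", paste(missing_cal, collapse = ", "))
  if (any(voxel_size_um[sp] <= 0) || any(!is.finite(voxel_size_um[sp])))
    stop("voxel sizes must be positive")
  if ("t" %in% axes) {
    if (is.null(frame_interval_s) || frame_interval_s <= 0)
      stop("frame_interval_s must be positive when a t axis is present")
  } else frame_interval_s <- NULL
  bit_depth <- as.integer(bit_depth)
  if (is.integer(data) &&
      (min(data) < 0 || max(data) > 2^bit_depth - 1))
    stop("integer intensities exceed the stated bit depth")
  structure(list(data = data, axes = axes,
                 voxel_size_um = voxel_size_um[intersect(c("x", "y", "z"),
                                                         names(voxel_size_um))],
                 frame_interval_s = frame_interval_s,
                 bit_depth = bit_depth),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  if (is.null(d)) d <- length(x$data)
  cat("image_stack: ", paste(d, collapse = " x "),
      " [", paste(x$axes, collapse = ""), "]\n", sep = "")
  cat("  voxel size (um): ",
      paste(sprintf("%s=%g", names(x$voxel_size_um), x$voxel_size_um),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$frame_interval_s))
    cat("  frame interval (s): ", x$frame_interval_s, "\n", sep = "")
  cat("  bit depth: ", x$bit_depth, ", intensity range [",
      paste(signif(range(x$data), 5), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

axis_index <- function(stack, ax) {
  i <- match(ax, stack$axes)
  if (is.na(i)) stop("stack has no '", ax, "' axis")
  i
}

has_axis <- function(stack, ax) ax %in% stack$axes

# spacing (um) per array dimension; NA for the t axis
axis_spacing <- function(stack) {
  vapply(stack$axes, function(a)
    if (a == "t") NA_real_ else unname(stack$voxel_size_um[a]), numeric(1))
}

#' Permute the axes of an image stack
#'
#' Lossless axis reordering: permuting and permuting back restores the
#' original array.
#'
#' @param stack an [image_stack].
#' @param axes target axis order (string or character vector); must be a
#'   permutation of the current axes.
#' @return The permuted [image_stack].
#' @export
permute_stack <- function(stack, axes) {
  if (is.character(axes) && length(axes) == 1L && nchar(axes) > 1L)
    axes <- strsplit(axes, "")[[1]]
  if (!setequal(axes, stack$axes) || length(axes) != length(stack$axes))
    stop("target axes must be a permutation of ",
         paste(stack$axes, collapse = ""))
  perm <- match(axes, stack$axes)
  stack$data <- aperm(stack$data, perm)
  stack$axes <- axes
  stack
}

#' Read a calibrated TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF (8 or 16 bit) into an
#' [image_stack]. Pages are stacked along the third axis. Calibration can be
#' supplied directly or through a sidecar config file \code{<path>.cfg}
#' written by [write_stack()]; explicit arguments take precedence, and
#' sidecar metadata is used only when its rank agrees with the file.
#'
#' @param path TIFF file path.
#' @param axes axis labels for the array as stored, e.g. \code{"yx"},
#'   \code{"yxz"} or \code{"yxt"}.
#' @param voxel_size_um,frame_interval_s,bit_depth calibration; see
#'   [image_stack()]. Missing values fall back to the sidecar, then to 1 um
#'   voxels.
#' @return An [image_stack] with integer data.
#' @export
read_stack <- function(path, axes, voxel_size_um = NULL,
                       frame_interval_s = NULL, bit_depth = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(axes) && length(axes) == 1L && nchar(axes) > 1L)
    axes <- strsplit(axes, "")[[1]]
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  rank <- if (length(pages) > 1L) 3L else length(axes)
  if (length(axes) != rank && !(length(axes) == 3L && length(pages) == 1L))
    stop("rank mismatch: file has ", length(pages),
         " page(s) but axes_spec is rank ", length(axes))
  a <- array(0L, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) a[, , i] <- pages[[i]]
  if (length(axes) == 2L) a <- a[, , 1]
  storage.mode(a) <- "integer"

  side <- paste0(path, ".cfg")
  sc <- if (file.exists(side)) read_config(side) else list()
  sc_rank_ok <- is.null(sc$axes) || nchar(sc$axes) == length(axes)
  vs <- voxel_size_um
  if (is.null(vs) && sc_rank_ok) {
    vv <- c(x = sc$voxel_x_um, y = sc$voxel_y_um, z = sc$voxel_z_um)
    if (length(vv)) vs <- unlist(vv)
  }
  if (is.null(vs)) vs <- c(x = 1, y = 1, z = 1)
  if (is.null(frame_interval_s) && sc_rank_ok)
    frame_interval_s <- sc$frame_interval_s
  if (is.null(bit_depth)) {
    info <- tryCatch(attr(tiff::readTIFF(path, payload = FALSE),
                          "bits.per.sample"), error = function(e) NULL)
    bit_depth <- bit_depth %||% sc$bit_depth %||% info %||% 8L
  }
  image_stack(a, axes, voxel_size_um = vs,
              frame_interval_s = frame_interval_s, bit_depth = bit_depth)
}

#' Write a calibrated TIFF stack
#'
#' Writes an [image_stack] as a multi-page grayscale TIFF plus a sidecar
#' \code{<path>.cfg} holding the calibration, so that
#' [read_stack()] round-trips the data and metadata exactly for integer
#' stacks.
#'
#' @param stack an [image_stack] of rank 2 or 3.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  if (length(d) > 3L) stop("write_stack supports rank 2 or 3 stacks")
  scale <- 2^stack$bit_depth - 1
  a <- stack$data / scale
  pages <- if (length(d) == 2L) list(a) else
    lapply(seq_len(d[3]), function(i) a[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  cfg <- list(axes = paste(stack$axes, collapse = ""),
              bit_depth = stack$bit_depth)
  for (ax in names(stack$voxel_size_um))
    cfg[[paste0("voxel_", ax, "_um")]] <- unname(stack$voxel_size_um[ax])
  if (!is.null(stack$frame_interval_s))
    cfg$frame_interval_s <- stack$frame_interval_s
  write_config(cfg, paste0(path, ".cfg"))
  invisible(path)
}

#' Write a results table as CSV
#'
#' Columns carry their units in the header names (\code{_um}, \code{_um_s},
#' ...). An empty record set writes a header-only file.
#'
#' @param records data.frame (e.g. cell records or flow estimates).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) read.csv(path)

#' Run configuration
#'
#' Flat named list of the pipeline's tunable parameters, with documented
#' defaults, serializable to a \code{key=value} text file. Unknown names are
#' rejected so config files fail loudly on typos.
#'
#' @param ... overrides of the defaults listed by \code{run_config()}.
#' @return A named list of class \code{run_config}.
#' @details Defaults: contrast percentiles 0.5/99.5; background = mode of the
#'   lowest-decile histogram; low-signal exclusion factor 1.5; smoothing sigma
#'   1 xy-pixel; watershed marker depth 10\% of dynamic range; Hough bins 1
#'   degree x 1 px with 0.5 overlap suppression; Radon angle grid 0.25
#'   degrees; kymograph line width 3 px.
#' @export
run_config <- function(...) {
  defaults <- list(
    voxel_x_um = 0.5, voxel_y_um = 0.5, voxel_z_um = 0.34,
    frame_interval_s = 1 / 30, bit_depth = 8,
    contrast_low_pct = 0.5, contrast_high_pct = 99.5,
    low_signal_factor = 1.5,
    smooth_sigma_um = 0.5, marker_h_frac = 0.1,
    min_diameter_um = 3, max_diameter_um = 25,
    link_radius_factor = 0.6, area_ratio_min = 0.1,
    hough_angle_step_deg = 1, hough_rho_step_px = 1,
    hough_overlap_frac = 0.5, min_segment_length_um = 20,
    radon_angle_step_deg = 0.25, line_width_px = 3,
    min_rows = 3, confidence_min = 3,
    distance_bin_um = 5, seed = 1
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stop("unknown config parameter(s): ",
                        paste(bad, collapse = ", "))
  defaults[names(ov)] <- ov
  structure(defaults, class = "run_config")
}

#' Write a flat key=value config file
#' @param config named list (e.g. from [run_config()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, "=", paste(format(v, digits = 15, scientific = FALSE),
                         collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key=value config file
#' @param path config path.
#' @return Named list; values parsed as numeric where possible.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else
      if (val %in% c("TRUE", "FALSE")) as.logical(val) else val
  }
  out
}
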