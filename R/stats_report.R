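# Summary statistics: Tukey boxplots, paired comparisons, census overlays.

#' Tukey boxplot summary
#'
#' Quartiles by linear interpolation between order statistics
#' (\code{stats::quantile} type 7, the common plotting default); whiskers
#' extend to the most extreme data points within 1.5 x IQR of the box
#' edges; points beyond are outliers.
#'
#' @param values nonempty numeric vector.
#' @return Object of class \code{boxplot_summary}: \code{q1, median, q3,
#'   iqr, whisker_low, whisker_high, outliers, n}.
#' @examples
#' boxplot_summary(1:100)
#' @export
boxplot_summary <- function(values) {
  if (!length(values)) stop("empty input")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  structure(list(q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
                 whisker_low = min(inside), whisker_high = max(inside),
                 outliers = sort(values[values < lo_fence | values > hi_fence]),
                 n = length(values)),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf(
    "boxplot_summary (n=%d): whiskers [%.4g, %.4g], box [%.4g, %.4g], median %.4g, %d outlier(s)\n",
    x$n, x$whisker_low, x$whisker_high, x$q1, x$q3, x$median,
    length(x$outliers)))
  invisible(x)
}

#' Paired sample t test
#'
#' Classical two-sided paired t test on the within-pair differences
#' (\code{post - pre}). Zero-variance differences (including identical
#' pairs) are reported as an exact-equality signal rather than a t
#' statistic.
#'
#' @param pre_values,post_values paired numeric vectors of equal length
#'   (>= 2), pairing order meaningful.
#' @return list: \code{t}, \code{df}, \code{p_value}, \code{mean_difference}
#'   (post - pre), \code{zero_variance}.
#' @examples
#' paired_t_test(c(10, 12, 14), c(8, 9, 12))
#' @export
paired_t_test <- function(pre_values, post_values) {
  if (length(pre_values) != length(post_values)) stop("length mismatch")
  if (length(pre_values) < 2) stop("need at least 2 pairs")
  d <- post_values - pre_values
  if (sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1L, p_value = NA_real_,
                mean_difference = mean(d), zero_variance = TRUE))
  }
  tt <- t.test(post_values, pre_values, paired = TRUE,
               alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d),
       zero_variance = FALSE)
}

#' Compare two cell censuses (e.g. before and after LPS)
#'
#' Pairs matched ROIs (same physical volume within 1\%), runs a paired t
#' test on the per-ROI densities, and overlays the pooled diameter
#' histograms on common bins.
#'
#' @param pre,post a [cell_census()] or list of censuses (matched ROIs, in
#'   pairing order).
#' @param threshold_um small-cell diameter threshold (default 10 um).
#' @return list: \code{density_test} (from [paired_t_test()]; NULL with a
#'   single ROI pair), \code{density_change_per_um3},
#'   \code{fraction_below_change}, \code{histogram_overlay} (data.frame
#'   \code{bin_low_um, bin_high_um, pre_count, post_count}).
#' @export
census_comparison <- function(pre, post, threshold_um = 10) {
  if (inherits(pre, "cell_census")) pre <- list(pre)
  if (inherits(post, "cell_census")) post <- list(post)
  if (length(pre) != length(post)) stop("unmatched ROI lists")
  for (i in seq_along(pre)) {
    v1 <- pre[[i]]$roi_volume_um3; v2 <- post[[i]]$roi_volume_um3
    if (abs(v1 - v2) / v1 > 0.01)
      stop("ROI volume mismatch above 1% in pair ", i)
  }
  dens_pre <- vapply(pre, function(c) c$density$density_cells_per_um3,
                     numeric(1))
  dens_post <- vapply(post, function(c) c$density$density_cells_per_um3,
                      numeric(1))
  test <- if (length(dens_pre) >= 2) paired_t_test(dens_pre, dens_post)
    else NULL
  dia <- function(lst) unlist(lapply(lst, function(c)
    c$cells$equivalent_diameter_um %||% c$cells$diameter_um))
  d1 <- dia(pre); d2 <- dia(post)
  fb1 <- if (length(d1)) mean(d1 < threshold_um) else NA_real_
  fb2 <- if (length(d2)) mean(d2 < threshold_um) else NA_real_
  bw <- 2
  upper <- max(c(d1, d2, bw)) + bw
  breaks <- seq(0, ceiling(upper / bw) * bw, by = bw)
  h1 <- hist(d1, breaks = breaks, plot = FALSE)$counts
  h2 <- hist(d2, breaks = breaks, plot = FALSE)$counts
  list(density_test = test,
       density_change_per_um3 = mean(dens_post - dens_pre),
       pre_density_per_um3 = dens_pre, post_density_per_um3 = dens_post,
       fraction_below_pre = fb1, fraction_below_post = fb2,
       fraction_below_change = fb2 - fb1,
       histogram_overlay = data.frame(bin_low_um = head(breaks, -1),
                                      bin_high_um = breaks[-1],
                                      pre_count = h1, post_count = h2))
}
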