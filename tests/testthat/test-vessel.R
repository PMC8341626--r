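test_that("temporal average collapses the t axis correctly", {
  a <- array(0L, c(4, 4, 2)); a[, , 2] <- 255L
  s <- image_stack(a, "yxt", voxel_size_um = c(x = 1, y = 1),
                   frame_interval_s = 1 / 30)
  avg <- temporal_average(s)
  expect_true(all(avg$data == 127.5))
  expect_identical(avg$axes, c("y", "x"))
  cst <- image_stack(array(9L, c(3, 3, 5)), "yxt",
                     voxel_size_um = c(x = 1, y = 1), frame_interval_s = 1)
  expect_true(all(temporal_average(cst)$data == 9))
})

test_that("vessel segmentation recovers a clean tube and ignores speckle", {
  img <- matrix(100, 64, 128)
  truth <- matrix(FALSE, 64, 128)
  truth[29:37, 10:118] <- TRUE
  img[truth] <- 220
  s <- image_stack(array(as.integer(img), dim(img)), "yx",
                   voxel_size_um = c(x = 1, y = 1))
  m <- segment_vessels(s, params = list(smooth_sigma_um = 0))
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_equal(dice, 1.0)
  # speckles below min_size_voxels do not change the mask
  img2 <- img
  set.seed(2)
  spk <- cbind(sample(1:20, 8), sample(1:128, 8))
  img2[spk] <- 220
  s2 <- image_stack(array(as.integer(img2), dim(img2)), "yx",
                    voxel_size_um = c(x = 1, y = 1))
  m2 <- segment_vessels(s2, params = list(smooth_sigma_um = 0))
  expect_identical(m2, m)
  # blank image signals an empty network
  blank <- image_stack(matrix(100L, 32, 32), "yx",
                       voxel_size_um = c(x = 1, y = 1))
  mb <- segment_vessels(blank, method = "fixed",
                        params = list(threshold = 300, smooth_sigma_um = 0))
  expect_true(isTRUE(attr(mb, "empty")))
})

test_that("skeletonization thins tubes to their axes, preserving topology", {
  m <- matrix(FALSE, 40, 80)
  m[18:24, 6:74] <- TRUE # straight tube, radius 3, axis at row 21
  sk <- skeletonize_network(m)
  expect_true(all(m[sk])) # skeleton subset of mask
  px <- which(sk, arr.ind = TRUE)
  inner <- px[px[, 2] > 10 & px[, 2] < 70, ]
  expect_lte(max(abs(inner[, 1] - 21)), 1) # within 1 px of the true axis
  # single voxel maps to itself
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_identical(skeletonize_network(one), one)
  # Y junction: exactly one branch point with 3+ neighbors
  ym <- matrix(FALSE, 60, 60)
  ym[28:32, 5:30] <- TRUE
  for (i in 0:20) ym[(28:32) - i, 30 + i] <- TRUE
  for (i in 0:20) ym[(28:32) + i, 30 + i] <- TRUE
  ysk <- skeletonize_network(ym)
  # count neighbors of each skeleton pixel
  nb <- matrix(0, nrow(ysk), ncol(ysk))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nrow(ysk), ncol(ysk))
    rs <- max(1, 1 + dr):min(nrow(ysk), nrow(ysk) + dr)
    cs <- max(1, 1 + dc):min(ncol(ysk), ncol(ysk) + dc)
    sh[rs, cs] <- ysk[rs - dr, cs - dc]
    nb <- nb + sh
  }
  # the 3+-neighbor pixels form exactly one junction zone
  br <- ysk & nb >= 3
  expect_gte(sum(br), 1)
  expect_equal(max(negcontrast:::label_components(br)), 1)
  comp_mask <- max(negcontrast:::label_components(ym))
  comp_skel <- max(negcontrast:::label_components(ysk))
  expect_equal(comp_skel, comp_mask)
  expect_error(skeletonize_network(matrix(FALSE, 4, 4)), "empty")
})

test_that("Hough segment selection recovers straight lines deterministically", {
  sk <- matrix(FALSE, 60, 60)
  sk[30, 5:54] <- TRUE # one horizontal 50-px line
  segs <- select_vessel_segments(sk, min_length_um = 20)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$angle_deg, 90, tolerance = 1) # within angular bin
  expect_gte(segs[[1]]$length_um, 45)
  # two perpendicular lines
  sk2 <- sk
  sk2[5:54, 12] <- TRUE
  segs2 <- select_vessel_segments(sk2, min_length_um = 20)
  expect_length(segs2, 2)
  expect_setequal(round(vapply(segs2, `[[`, numeric(1), "angle_deg")),
                  c(0, 90))
  # empty skeleton
  expect_length(select_vessel_segments(matrix(FALSE, 10, 10)), 0)
  # deterministic
  expect_identical(select_vessel_segments(sk2, min_length_um = 20),
                   select_vessel_segments(sk2, min_length_um = 20))
})

test_that("segment selection is equivariant to translation", {
  sk <- matrix(FALSE, 80, 80)
  sk[cbind(20 + 0:40, 15 + 0:40)] <- TRUE # diagonal line
  s1 <- select_vessel_segments(sk, min_length_um = 20)
  sh <- matrix(FALSE, 80, 80)
  sh[cbind(25 + 0:40, 22 + 0:40)] <- TRUE # shifted by (5, 7)
  s2 <- select_vessel_segments(sh, min_length_um = 20)
  expect_length(s1, 1); expect_length(s2, 1)
  expect_equal(s2[[1]]$angle_deg, s1[[1]]$angle_deg)
  expect_equal(s2[[1]]$length_um, s1[[1]]$length_um, tolerance = 2)
  shift <- colMeans(s2[[1]]$polyline) - colMeans(s1[[1]]$polyline)
  expect_equal(unname(shift), c(7, 5), tolerance = 1)
})
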