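test_that("LUT inversion is an exact involution within the bit depth", {
  a <- array(sample.int(256, 200, replace = TRUE) - 1L, c(10, 20))
  s <- image_stack(a, "yx", voxel_size_um = c(x = 1, y = 1))
  inv <- invert_lut(s)
  expect_equal(inv$data, 255L - a)
  expect_identical(invert_lut(inv)$data, a)
  # boundary: 0 -> 255
  expect_equal(invert_lut(image_stack(matrix(0L, 2, 2), "yx",
               voxel_size_um = c(x = 1, y = 1)))$data, matrix(255L, 2, 2))
  # rank order is exactly reversed
  expect_equal(rank(inv$data), rank(-a))
  expect_error(invert_lut(image_stack(matrix(70000L, 1, 1), "yx",
               voxel_size_um = c(x = 1, y = 1), bit_depth = 16), bit_depth = 8),
               "bit depth")
})

test_that("contrast enhancement rescales percentiles to full range, monotonically", {
  two <- matrix(c(rep(50L, 50), rep(150L, 50)), 10, 10)
  s <- image_stack(two, "yx", voxel_size_um = c(x = 1, y = 1))
  e <- enhance_contrast(s, 0, 100)
  expect_setequal(unique(as.vector(e$data)), c(0L, 255L))
  # full-range image with (0, 100) is unchanged
  full <- matrix(as.integer(round(seq(0, 255, length.out = 64))), 8, 8)
  s2 <- image_stack(full, "yx", voxel_size_um = c(x = 1, y = 1))
  expect_equal(enhance_contrast(s2, 0, 100)$data, full)
  # constant image unchanged with warning
  cst <- image_stack(matrix(7L, 5, 5), "yx", voxel_size_um = c(x = 1, y = 1))
  expect_warning(out <- enhance_contrast(cst), "constant")
  expect_identical(out$data, cst$data)
  # monotone among non-clipped values
  set.seed(1)
  r <- matrix(sample.int(200, 400, replace = TRUE) + 20L, 20, 20)
  s3 <- image_stack(r, "yx", voxel_size_um = c(x = 1, y = 1))
  e3 <- enhance_contrast(s3, 5, 95)
  mid <- r > quantile(r, 0.05) & r < quantile(r, 0.95)
  expect_true(all(diff(e3$data[mid][order(r[mid])]) >= 0))
})

test_that("background estimate finds the dark-population floor", {
  cfg <- small_marrow_config(seed = 4, noise_sd = 0)
  sc <- generate_marrow_phantom(cfg)
  expect_equal(estimate_background(sc$stack), cfg$cell_level)
  expect_equal(estimate_background(matrix(42L, 10, 10)), 42L)
  # robust to isolated dark outliers, unlike the global minimum
  a <- matrix(200L, 50, 50); a[1, 1] <- 0L; a[2:60] <- 180L
  expect_gt(estimate_background(a), 0)
  excl <- matrix(TRUE, 20, 20); excl[1, 1] <- FALSE
  expect_error(estimate_background(matrix(1L, 20, 20), excl),
               "99")
})

test_that("vessel-signal removal replaces only masked voxels with background", {
  cfg <- small_marrow_config(seed = 6, cell_count = 10,
    vessel_paths = list(list(points = cbind(x = c(5, 45), y = c(25, 25),
                                            z = c(7, 7)), radius_um = 4)))
  sc <- generate_marrow_phantom(cfg)
  out <- remove_vessel_signal(sc$stack, sc$truth_vessel_mask, background = 40)
  expect_true(all(out$data[sc$truth_vessel_mask] == 40))
  expect_identical(out$data[!sc$truth_vessel_mask],
                   sc$stack$data[!sc$truth_vessel_mask])
  # empty and full masks
  empty <- array(FALSE, dim(sc$stack$data))
  expect_identical(remove_vessel_signal(sc$stack, empty)$data, sc$stack$data)
  full <- remove_vessel_signal(sc$stack, !empty, background = 40)
  expect_true(all(full$data == 40))
  expect_error(remove_vessel_signal(sc$stack, matrix(TRUE, 2, 2)), "mismatch")
})

test_that("exclusion masks union bone, vessel and low-signal criteria", {
  a <- array(200L, c(10, 10, 4))
  s <- image_stack(a, "yxz", voxel_size_um = c(x = 1, y = 1, z = 1))
  expect_warning(m0 <- build_exclusion_mask(s), "no exclusion criteria")
  expect_false(any(m0$mask))
  vm <- array(FALSE, dim(a)); vm[1:3, 1:3, ] <- TRUE
  m1 <- build_exclusion_mask(s, vessel_mask = vm)
  expect_true(all(m1$mask[vm]))
  expect_identical(m1$provenance, "vessel")
  # threshold above the maximum excludes everything
  m2 <- build_exclusion_mask(s, low_signal_threshold = 300)
  expect_true(all(m2$mask))
  # bone channel thresholding
  bone <- array(0L, dim(a)); bone[8:10, 8:10, ] <- 250L
  m3 <- build_exclusion_mask(s, bone_channel = bone, vessel_mask = vm)
  expect_true(all(m3$mask[bone > 0]))
  expect_setequal(m3$provenance, c("bone", "vessel"))
})
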