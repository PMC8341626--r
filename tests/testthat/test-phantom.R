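test_that("marrow phantom renders dark cells with full ground truth", {
  cfg <- small_marrow_config(seed = 3, noise_sd = 0)
  sc <- generate_marrow_phantom(cfg)
  expect_equal(nrow(sc$truth_cells), cfg$cell_count)
  # every truth cell lies inside the volume
  expect_true(all(sc$truth_cells$x_um > 0 & sc$truth_cells$x_um < 50))
  expect_true(all(sc$truth_cells$z_um > 0 & sc$truth_cells$z_um < 14))
  # direct voxel scan: cell-interior voxels are darker than the interstitium
  expect_true(all(sc$stack$data[sc$truth_cell_mask] < cfg$interstitium_level))
  expect_true(max(sc$stack$data) >= cfg$interstitium_level - 1)
  # empty scene
  sc0 <- generate_marrow_phantom(phantom_config(
    volume_um = c(x = 20, y = 20, z = 8), cell_count = 0, noise_sd = 0))
  expect_equal(nrow(sc0$truth_cells), 0)
  expect_true(all(sc0$stack$data == sc0$config$interstitium_level))
})

test_that("phantom generation is deterministic per seed", {
  a <- generate_marrow_phantom(small_marrow_config(seed = 11))
  b <- generate_marrow_phantom(small_marrow_config(seed = 11))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth_cells, b$truth_cells)
  c <- generate_marrow_phantom(small_marrow_config(seed = 12))
  expect_false(identical(a$stack$data, c$stack$data))
  # placement-only sampling reproduces the rendered truth
  expect_equal(sample_cell_packing(small_marrow_config(seed = 11))[,
               c("x_um", "y_um", "z_um", "radius_um")],
               a$truth_cells[, c("x_um", "y_um", "z_um", "radius_um")])
})

test_that("noiseless non-overlapping phantom is self-consistent at midpoint threshold", {
  cfg <- phantom_config(volume_um = c(x = 60, y = 60, z = 15),
                        cell_count = 22, overlap_tolerance = 0,
                        noise_sd = 0, seed = 5)
  sc <- generate_marrow_phantom(cfg)
  mid <- (cfg$interstitium_level + cfg$cell_level) / 2
  dark <- sc$stack$data < mid
  lab <- negcontrast:::label_components(dark)
  expect_equal(max(lab), cfg$cell_count)
  vox <- cfg$voxel_size_um[c("y", "x", "z")]
  idx <- which(lab > 0)
  co <- arrayInd(idx, dim(lab))
  for (ax in 1:3) co[, ax] <- (co[, ax] - 0.5) * vox[ax]
  cent <- data.frame(
    y_um = tapply(co[, 1], lab[idx], mean),
    x_um = tapply(co[, 2], lab[idx], mean),
    z_um = tapply(co[, 3], lab[idx], mean))
  # cells clipped by the optical-section faces have shifted mass centroids;
  # check the sub-voxel recovery on the unclipped ones
  unclipped <- sc$truth_cells$z_um > sc$truth_cells$radius_um &
    sc$truth_cells$z_um < 15 - sc$truth_cells$radius_um
  err <- nearest_match_distances(sc$truth_cells[unclipped, ], cent)
  expect_gt(sum(unclipped), 5)
  expect_lt(max(err), 0.5 * sqrt(sum(vox^2))) # within half a voxel diagonal
})

test_that("sub-threshold voxel count grows with cell count", {
  counts <- c(5, 15, 30)
  dark <- vapply(counts, function(n) {
    sc <- generate_marrow_phantom(phantom_config(
      volume_um = c(x = 50, y = 50, z = 14), cell_count = n,
      noise_sd = 0, seed = 8))
    sum(sc$stack$data < 120)
  }, numeric(1))
  expect_true(all(diff(dark) >= 0))
})

test_that("flow series moves discs by v * dt along the path", {
  cfg <- flow_phantom_config(speeds_um_s = 300, frame_rate_fps = 120,
                             duration_s = 0.1, seed = 2, noise_sd = 0,
                             rbc_spacing_um = 120)
  cfg$vessel_paths <- list(list(points = cbind(x = c(14, 242), y = c(64, 64)),
                                radius_um = 4))
  sc <- generate_flow_series(cfg)
  a <- sc$stack$data
  # dark-pixel x centroid drift per frame = 300 um/s / 120 fps = 2.5 um
  cx <- vapply(seq_len(dim(a)[3]), function(f) {
    dk <- which(a[, , f] < 80, arr.ind = TRUE)
    mean((dk[, 2] - 0.5) * 1.0)
  }, numeric(1))
  drift <- diff(cx)
  drift <- drift[abs(drift) < 10] # exclude wrap-around frames
  expect_equal(mean(drift), 2.5, tolerance = 0.15)
  # v = 0: footprint identical in all frames (noiseless)
  cfg0 <- cfg; cfg0$flow_speeds_um_s <- 0
  s0 <- generate_flow_series(cfg0)
  for (f in 2:dim(s0$stack$data)[3])
    expect_identical(s0$stack$data[, , f], s0$stack$data[, , 1])
  # negating v gives the time-reversed sequence (noiseless, symmetric train)
  expect_error(generate_flow_series({
    bad <- cfg; bad$flow_speeds_um_s <- 1e6; bad
  }), "traverses")
})

test_that("bleaching multiplies masked voxels by (1 - rate)^frame", {
  a <- array(1000, c(4, 4, 11))
  s <- image_stack(a, "yxt", voxel_size_um = c(x = 1, y = 1),
                   frame_interval_s = 1)
  mask <- matrix(FALSE, 4, 4); mask[1:2, ] <- TRUE
  out <- apply_bleaching(s, 0.1, mask)
  expect_equal(out$data[1, 1, 11], 1000 * 0.9^10) # ~348.68
  expect_equal(out$data[4, 4, 11], 1000)          # outside untouched
  # rate 0 and empty mask are identities
  expect_equal(apply_bleaching(s, 0, mask)$data, a)
  expect_equal(apply_bleaching(s, 0.3, mask & FALSE)$data, a)
  expect_error(apply_bleaching(s, 1, mask), "rate")
})
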