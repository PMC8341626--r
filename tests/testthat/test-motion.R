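make_series <- function(a, fps = 30) {
  image_stack(a, "yxt", voxel_size_um = c(x = 1, y = 1),
              frame_interval_s = 1 / fps)
}

test_that("standard-deviation map matches closed forms and frame-order invariance", {
  cst <- make_series(array(77, c(4, 4, 6)))
  expect_true(all(std_dev_map(cst)$data == 0))
  # alternating {0, 255} over 2 frames: sample sd = 180.31
  alt <- array(0, c(2, 2, 2)); alt[, , 2] <- 255
  expect_equal(std_dev_map(make_series(alt))$data[1, 1], 180.3122,
               tolerance = 1e-4)
  set.seed(4)
  a <- array(rnorm(4 * 4 * 10), c(4, 4, 10))
  s1 <- std_dev_map(make_series(a))
  s2 <- std_dev_map(make_series(a[, , sample(10)]))
  expect_equal(s1$data, s2$data)
  expect_error(std_dev_map(make_series(array(0, c(2, 2, 1)))), "2 frames")
})

test_that("motion map highlights the vessel lumen of a flow series", {
  sc <- generate_flow_series(flow_phantom_config(seed = 3, duration_s = 0.5))
  sdm <- std_dev_map(sc$stack)
  expect_gt(mean(sdm$data[sc$truth_vessel_mask]),
            3 * mean(sdm$data[!sc$truth_vessel_mask]))
})

test_that("digital line scan produces calibrated kymographs", {
  # stationary dark disc: vertical dark stripe at a fixed column
  a <- array(200, c(40, 80, 12))
  for (f in 1:12) a[18:22, 38:42, f] <- 40
  s <- make_series(a, fps = 120)
  seg <- cbind(x = c(5, 75), y = c(19.5, 19.5))
  ky <- digital_line_scan(s, seg)
  expect_s3_class(ky, "kymograph")
  expect_equal(nrow(ky$data), 12)
  mins <- apply(ky$data, 1, which.min)
  expect_equal(length(unique(mins)), 1) # stripe column constant over time
  # uniform series gives a constant kymograph
  u <- make_series(array(123, c(20, 40, 10)))
  kyu <- digital_line_scan(u, cbind(x = c(5, 35), y = c(10, 10)))
  expect_true(all(abs(kyu$data - 123) < 1e-9))
  # segment leaving the field of view errors
  expect_error(digital_line_scan(u, cbind(x = c(5, 60), y = c(10, 10))),
               "field of view")
})

test_that("Radon slope estimation matches the shear-and-project oracle", {
  for (slope in c(-2, -0.5, 0, 0.3, 1, 2)) {
    K <- stripe_kymograph(64, 64, slope)
    r <- radon_slope(K, angle_step_deg = 0.25)
    expect_equal(r$angle_deg, atan(slope) * 180 / pi, tolerance = 0.3)
    oracle <- shear_project_angle(K, seq(-89.75, 89.75, by = 0.25))
    expect_equal(r$angle_deg, oracle, tolerance = 0.26)
  }
  # noisy case: estimator and oracle still agree on the angle
  K <- stripe_kymograph(64, 64, 1.5, noise_sd = 10, seed = 2)
  r <- radon_slope(K, angle_step_deg = 0.25)
  oracle <- shear_project_angle(K, seq(-89.75, 89.75, by = 0.25))
  expect_equal(r$angle_deg, oracle, tolerance = 0.51)
})

test_that("Radon slope obeys its symmetries and degenerate cases", {
  K <- stripe_kymograph(32, 48, 1.2)
  r <- radon_slope(K)
  rm <- radon_slope(K[, ncol(K):1]) # mirrored kymograph: negated slope
  expect_equal(rm$slope_px_per_frame, -r$slope_px_per_frame, tolerance = 0.05)
  # sharp vertical stripes: angle and slope exactly zero
  set.seed(9)
  v <- matrix(rep(sample(c(60, 200), 48, replace = TRUE), each = 32), 32, 48)
  expect_equal(radon_slope(v)$angle_deg, 0)
  expect_equal(radon_slope(v)$slope_px_per_frame, 0)
  # flat kymograph: no estimate, zero confidence
  flat <- radon_slope(matrix(5, 20, 30))
  expect_false(flat$ok)
  expect_equal(flat$confidence, 0)
  expect_error(radon_slope(matrix(0, 4, 30)), "8 rows")
})

test_that("slope-to-speed conversion and the reportable-speed bound are exact", {
  expect_equal(speed_from_slope(0, 0.5, 1 / 120), 0)
  expect_equal(speed_from_slope(2, 0.5, 1 / 120), 120)
  expect_equal(speed_from_slope(2, 0.5, 1 / 120, orientation_sign = -1), -120)
  expect_equal(max_reportable_speed(120, 25, 3), 1000)
  expect_equal(max_reportable_speed(240, 25, 3),
               2 * max_reportable_speed(120, 25, 3))
  # min_rows = row count: v_max = length / duration
  expect_equal(max_reportable_speed(120, 25, 240), 25 / 2)
})

test_that("rolling velocity is flat for constant flow and zero for stationary cells", {
  cfg <- flow_phantom_config(speeds_um_s = 250, frame_rate_fps = 120,
                             duration_s = 1, seed = 6)
  cfg$vessel_paths <- cfg$vessel_paths[1]
  sc <- generate_flow_series(cfg)
  net <- build_vessel_network(sc$stack, min_length_um = 60)
  ky <- digital_line_scan(sc$stack, net$segments[[1]])
  rv <- rolling_velocity_series(ky, window_s = 0.2, step_s = 0.1)
  sp <- abs(rv$speed_um_s[!is.na(rv$speed_um_s)])
  expect_gt(length(sp), 5)
  expect_true(all(abs(sp - 250) / 250 < 0.1))
  # stationary: all confident estimates are zero
  cfg0 <- cfg; cfg0$flow_speeds_um_s <- 0
  sc0 <- generate_flow_series(cfg0)
  ky0 <- digital_line_scan(sc0$stack, net$segments[[1]])
  rv0 <- rolling_velocity_series(ky0, window_s = 0.2, step_s = 0.1)
  expect_true(all(abs(rv0$speed_um_s[!is.na(rv0$speed_um_s)]) < 5))
})

test_that("bleaching kinetics normalize to 1 at t0 and separate compartments", {
  cfg <- phantom_config(volume_um = c(x = 50, y = 50, z = 10),
                        cell_count = 12, bleaching_rate = 0.1,
                        frame_rate_fps = 1, seed = 2)
  bl <- generate_bleaching_series(cfg, n_frames = 40)
  bk <- bleaching_kinetics(bl$stack,
                           list(cells = bl$truth_cell_mask,
                                interstitium = bl$truth_interstitium_mask))
  first <- subset(bk$curves, frame == 0)
  expect_true(all(first$normalized_intensity == 1))
  expect_equal(unname(bk$rates_per_frame["cells"]), 0.1, tolerance = 0.01)
  expect_lt(abs(bk$rates_per_frame["interstitium"]), 0.005)
  # rate 0 everywhere: both curves stay near 1
  cfg0 <- cfg; cfg0$bleaching_rate <- 0
  bl0 <- generate_bleaching_series(cfg0, n_frames = 15)
  bk0 <- bleaching_kinetics(bl0$stack, list(cells = bl0$truth_cell_mask))
  expect_true(all(abs(bk0$curves$normalized_intensity - 1) < 0.05))
  expect_error(bleaching_kinetics(bl$stack,
               list(bad = bl$truth_cell_mask & FALSE)), "empty")
})
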