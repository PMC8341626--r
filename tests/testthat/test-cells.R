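test_that("watershed separates touching dark discs across a bright ridge", {
  img <- disc_image(40, 60, centers = rbind(c(20, 20), c(20, 32)), radius = 5)
  lab <- detect_cells_2d(img, params = list(smooth_sigma_um = 0.8))
  reg <- attr(lab, "regions")
  expect_equal(nrow(reg), 2)
  cent <- reg[order(reg$x_um), ]
  expect_lt(abs(cent$x_um[1] - 19.5), 1) # (index - 0.5) * 1 um
  expect_lt(abs(cent$x_um[2] - 31.5), 1)
  expect_lt(abs(cent$y_um[1] - 19.5), 1)
  # uniform bright slice has no cells
  lab0 <- detect_cells_2d(matrix(200, 30, 30))
  expect_equal(max(lab0), 0)
  expect_equal(nrow(attr(lab0, "regions")), 0)
})

test_that("every foreground pixel belongs to at most one label", {
  cfg <- small_marrow_config(seed = 9)
  sc <- generate_marrow_phantom(cfg)
  z <- ceiling(dim(sc$stack$data)[3] / 2)
  lab <- detect_cells_2d(sc$stack$data[, , z],
                         voxel_size_um = cfg$voxel_size_um)
  expect_true(all(lab >= 0))
  reg <- attr(lab, "regions")
  expect_equal(sum(tabulate(lab[lab > 0])), sum(lab > 0))
  expect_equal(nrow(reg), max(lab))
})

test_that("detection is equivariant to LUT inversion with flipped polarity", {
  cfg <- small_marrow_config(seed = 10)
  sc <- generate_marrow_phantom(cfg)
  z <- ceiling(dim(sc$stack$data)[3] / 2)
  sl <- sc$stack$data[, , z]
  lab_dark <- detect_cells_2d(sl, voxel_size_um = cfg$voxel_size_um)
  lab_bright <- detect_cells_2d(255L - sl,
                                params = list(polarity = "bright"),
                                voxel_size_um = cfg$voxel_size_um)
  expect_identical(unclass(lab_dark)[], unclass(lab_bright)[])
})

test_that("3D packing reduces a sphere's sections to one correct record", {
  cfg <- phantom_config(volume_um = c(x = 20, y = 20, z = 16),
                        voxel_size_um = c(x = 0.5, y = 0.5, z = 0.34),
                        cell_count = 0, noise_sd = 0, seed = 1)
  sc <- generate_marrow_phantom(cfg,
    cells = data.frame(x_um = 10, y_um = 10, z_um = 8, radius_um = 4))
  rec <- detect_cells_stackwise(sc$stack, params = list(threshold = 120))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$equivalent_diameter_um, 8, tolerance = 0.8) # within 10%
  expect_lt(abs(rec$z_um - 8), 0.34)                           # within dz
  expect_lt(abs(rec$x_um - 10), 0.5)
  # two spheres stacked with a 12 um center gap in z stay separate
  cfg2 <- phantom_config(volume_um = c(x = 20, y = 20, z = 22),
                         voxel_size_um = c(x = 0.5, y = 0.5, z = 0.34),
                         cell_count = 0, noise_sd = 0, seed = 1)
  sc2 <- generate_marrow_phantom(cfg2,
    cells = data.frame(x_um = c(10, 10), y_um = c(10, 10),
                       z_um = c(5, 17), radius_um = c(3, 3)))
  rec2 <- detect_cells_stackwise(sc2$stack, params = list(threshold = 120))
  expect_equal(nrow(rec2), 2)
  expect_equal(sort(rec2$z_um), c(5, 17), tolerance = 0.5)
  # empty labeling on all slices gives an empty record set
  blank <- image_stack(array(200L, c(20, 20, 6)), "yxz",
                       voxel_size_um = c(x = 1, y = 1, z = 1))
  expect_equal(nrow(detect_cells_stackwise(blank)), 0)
})

test_that("3D segmentation recovers a single sphere's volume", {
  cfg <- phantom_config(volume_um = c(x = 20, y = 20, z = 16),
                        voxel_size_um = c(x = 0.5, y = 0.5, z = 0.34),
                        cell_count = 0, noise_sd = 0, seed = 1)
  sc <- generate_marrow_phantom(cfg,
    cells = data.frame(x_um = 10, y_um = 10, z_um = 8, radius_um = 4))
  # global-histogram thresholds are degenerate for a single small object
  # in a large field, so the foreground threshold is given explicitly
  seg <- segment_cells_3d(sc$stack, params = list(threshold = 120))
  expect_equal(nrow(seg$cells), 1)
  v_true <- 4 / 3 * pi * 4^3
  expect_lt(abs(seg$cells$volume_um3 - v_true) / v_true, 0.15)
  expect_equal(seg$cells$x_um, 10, tolerance = 0.5)
  # fully excluded volume yields nothing
  seg0 <- segment_cells_3d(sc$stack, params = list(threshold = 120),
    exclusion = exclusion_mask(array(TRUE, dim(sc$stack$data)), "bone"))
  expect_equal(nrow(seg0$cells), 0)
})

test_that("density, diameter fraction and per-cell intensity follow their definitions", {
  d <- cell_density(data.frame(x = 1:10), 100 * 100 * 20)
  expect_equal(d$density_cells_per_um3, 5e-5)
  expect_equal(d$cells_per_standard_roi, 10)
  expect_equal(cell_density(data.frame(), 1000)$count, 0)
  expect_equal(cell_density(10, 2 * 100 * 100 * 20)$cells_per_standard_roi, 5)
  expect_error(cell_density(data.frame(), 0), "positive")

  expect_equal(diameter_fraction_below(
    data.frame(equivalent_diameter_um = rep(8, 5)))$fraction, 1)
  expect_equal(diameter_fraction_below(
    data.frame(equivalent_diameter_um = c(8, 12)))$fraction, 0.5)
  expect_error(diameter_fraction_below(data.frame()), "empty")

  lab <- matrix(0L, 4, 4); lab[1, 1:3] <- 1L; lab[3, 1:2] <- 2L
  img <- matrix(0, 4, 4); img[1, 1:3] <- c(10, 20, 30)
  img[3, 1:2] <- c(0, 255)
  pci <- per_cell_intensity(lab, img)
  expect_equal(pci$mean_intensity, c(20, 127.5))
  expect_equal(pci$n_px, c(3L, 2L))
  uni <- per_cell_intensity(matrix(1L, 2, 2), matrix(40, 2, 2))
  expect_equal(uni$mean_intensity, 40)
})

test_that("phantom sections through sphere equators are each detected", {
  cfg <- phantom_config(volume_um = c(x = 60, y = 60, z = 12),
                        cell_count = 8, noise_sd = 0,
                        overlap_tolerance = 0, seed = 14)
  sc <- generate_marrow_phantom(cfg)
  # slice through each truth equator: the section there has >= that cell
  hits <- 0
  for (i in seq_len(nrow(sc$truth_cells))) {
    z <- round(sc$truth_cells$z_um[i] / 0.34 + 0.5)
    lab <- detect_cells_2d(sc$stack$data[, , z],
                           voxel_size_um = cfg$voxel_size_um)
    reg <- attr(lab, "regions")
    dd <- sqrt((reg$x_um - sc$truth_cells$x_um[i])^2 +
                 (reg$y_um - sc$truth_cells$y_um[i])^2)
    if (length(dd) && min(dd) < 2) hits <- hits + 1
  }
  expect_equal(hits, nrow(sc$truth_cells))
})
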