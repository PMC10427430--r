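test_that("mosaic formation follows Malus projection per micro-polarizer", {
  H <- 16; W <- 16
  m <- function(v) matrix(v, H, W)
  # unpolarized uniform scene: all four orientations equal
  sc <- stokes_image(m(1), m(0), m(0), m(0), mode = "full")
  mos <- simulate_dofp_mosaic(sc, exposure_scale = 100, quantize = FALSE)
  expect_equal(as.numeric(range(unclass(mos))), c(50, 50))
  # 0-degree linear scene: I0 sites maximal, I90 sites ~ 0
  sc2 <- stokes_image(m(1), m(1), m(0), m(0), mode = "full")
  mos2 <- unclass(simulate_dofp_mosaic(sc2, exposure_scale = 100,
                                       quantize = FALSE))
  expect_equal(mos2[2, 2], 100)  # bottom-right of super-pixel: 0 degrees
  expect_equal(mos2[1, 1], 0)    # top-left: 90 degrees
  expect_equal(mos2[1, 2], 50)   # 45 degrees sees half
  expect_error(simulate_dofp_mosaic(
    stokes_image(matrix(1, 3, 3), matrix(0, 3, 3), matrix(0, 3, 3),
                 matrix(0, 3, 3), mode = "full")), "even")
})

test_that("fixed-pattern correction inverts the gain/offset model", {
  H <- 32; W <- 32
  cal1 <- calibration_map(matrix(1, H, W))
  raw <- matrix(runif(H * W, 0, 200), H, W)
  expect_equal(unclass(correct_fixed_pattern(
    structure(raw, bitdepth = 8L, layout = dofp_layout()), cal1))[, ],
    raw)
  cal2 <- calibration_map(matrix(2, H, W))
  expect_equal(unclass(correct_fixed_pattern(
    structure(raw, bitdepth = 8L, layout = dofp_layout()), cal2))[, ],
    raw / 2)
  expect_error(correct_fixed_pattern(raw, calibration_map(matrix(1, 8, 8))),
               "dimensions")
})

test_that("flat-field calibration removes a random gain field", {
  H <- 64; W <- 64
  set.seed(5)
  gain <- matrix(runif(H * W, 0.8, 1.2), H, W)
  calib_true <- calibration_map(gain)
  m <- function(v) matrix(v, H, W)
  flat <- stokes_image(m(1), m(0), m(0), m(0), mode = "full")
  flat_frame <- simulate_dofp_mosaic(flat, calibration = calib_true,
                                     exposure_scale = 150, quantize = FALSE)
  calib_hat <- estimate_calibration(flat_frame)
  # noise-free flats identify the gain up to one scale per orientation
  alpha <- endopol:::layout_angle_map(dofp_layout(), H, W)
  for (a in unique(as.vector(dofp_layout()))) {
    idx <- abs(alpha - a) < 1e-12
    expect_equal(calib_hat$gain[idx],
                 gain[idx] / mean(gain[idx]), tolerance = 1e-12)
  }
  # correcting with the true calibration removes the fixed pattern entirely
  scene <- scene_to_stokes(uniform_truth(H, W, delta = pi / 4, theta = 0.3))
  raw <- simulate_dofp_mosaic(scene, calibration = calib_true,
                              exposure_scale = 150, quantize = FALSE)
  corrected <- correct_fixed_pattern(raw, calib_true)
  ideal <- simulate_dofp_mosaic(scene, exposure_scale = 150, quantize = FALSE)
  resid <- unclass(corrected) - unclass(ideal)
  expect_lt(stats::var(as.numeric(resid)) / stats::var(as.numeric(ideal)),
            1e-10)
})

test_that("bilinear demosaicing keeps native sites and reproduces affine ramps", {
  H <- 32; W <- 32
  # spatially constant per orientation
  sc <- stokes_image(matrix(1, H, W), matrix(0.3, H, W), matrix(0.1, H, W),
                     matrix(0, H, W), mode = "full")
  mos <- simulate_dofp_mosaic(sc, exposure_scale = 1, quantize = FALSE)
  sub <- demosaic_bilinear(mos)
  for (nm in names(sub)) expect_equal(stats::var(as.numeric(sub[[nm]])), 0)
  expect_equal(sub$I0[1, 1], 0.5 * (1 + 0.3))
  expect_equal(sub$I90[1, 1], 0.5 * (1 - 0.3))

  # affine intensity ramp is reproduced exactly away from the border
  ramp <- outer(seq_len(H), seq_len(W), function(i, j) 2 + 0.1 * i + 0.05 * j)
  sc2 <- stokes_image(ramp, ramp * 0, ramp * 0, ramp * 0, mode = "full")
  mos2 <- simulate_dofp_mosaic(sc2, exposure_scale = 2, quantize = FALSE)
  sub2 <- demosaic_bilinear(mos2)
  interior <- as.matrix(expand.grid(3:(H - 2), 3:(W - 2)))
  expect_equal(sub2$I45[interior], ramp[interior], tolerance = 1e-12)

  # native sites pass through unchanged; interpolated neighbours average
  x <- matrix(0, H, W); x[15, 15] <- 8   # (odd, odd) = 90-degree site
  sub3 <- demosaic_bilinear(x)
  expect_equal(sub3$I90[15, 15], 8)
  expect_equal(sub3$I90[15, 13], 0)
  expect_equal(sub3$I90[15, 14], 4)      # midway between two native columns
  expect_equal(sub3$I90[14, 14], 2)      # centre of four native sites
})

test_that("partial-Stokes reconstruction implements the sub-image sums", {
  one <- matrix(1, 4, 4); half <- matrix(0.5, 4, 4); zero <- matrix(0, 4, 4)
  ps <- partial_stokes_linear(structure(list(I0 = one, I45 = one, I90 = one,
                                             I135 = one),
                                        class = "sub_images"))
  expect_equal(ps$S0[1, 1], 2); expect_equal(ps$S1[1, 1], 0)
  ps2 <- partial_stokes_linear(structure(list(I0 = one, I45 = half,
                                              I90 = zero, I135 = half),
                                         class = "sub_images"))
  expect_equal(c(ps2$S0[1, 1], ps2$S1[1, 1], ps2$S2[1, 1]), c(1, 1, 0))
  ps3 <- partial_stokes_circular(structure(list(I0 = half, I45 = zero,
                                                I90 = half, I135 = zero),
                                           class = "sub_images"))
  expect_equal(c(ps3$S0[1, 1], ps3$S3[1, 1]), c(1, 0))
  ps4 <- partial_stokes_circular(structure(list(I0 = one, I45 = zero,
                                                I90 = zero, I135 = zero),
                                           class = "sub_images"))
  expect_equal(c(ps4$S0[1, 1], ps4$S3[1, 1]), c(1, 1))
})

test_that("a simulated 30-degree linear scene is recovered to machine precision", {
  H <- 32; W <- 32
  S <- apply_mueller(mueller_linear_polarizer(pi / 6), c(1, 0, 0, 0)) * 2
  m <- function(v) matrix(v, H, W)
  sc <- stokes_image(m(S[1]), m(S[2]), m(S[3]), m(S[4]), mode = "full")
  ps <- partial_stokes_linear(demosaic_bilinear(
    simulate_dofp_mosaic(sc, exposure_scale = 120, quantize = FALSE)))
  expect_equal(ps$S1[10, 10] / ps$S0[10, 10], S[2] / S[1], tolerance = 1e-12)
  expect_equal(ps$S2[10, 10] / ps$S0[10, 10], S[3] / S[1], tolerance = 1e-12)
})

test_that("a right-circular scene reads S3/S0 = 1 through the waveplate path", {
  H <- 16; W <- 16
  m <- function(v) matrix(v, H, W)
  sc <- stokes_image(m(1), m(0), m(0), m(1), mode = "full")
  ps <- partial_stokes_circular(demosaic_bilinear(
    simulate_dofp_mosaic(sc, mode = "depolarization", exposure_scale = 100,
                         quantize = FALSE)))
  expect_equal(max(abs(ps$S3 / ps$S0 - 1)), 0, tolerance = 1e-9)
})

test_that("retardance and depolarization maps implement their formulas", {
  ps <- stokes_image(matrix(1, 2, 2), matrix(c(0, 0.6, 0, 0.6), 2, 2),
                     matrix(0, 2, 2), mode = "retardance")
  am <- retardance_map(ps)
  expect_equal(am$values[1, 1], 0)
  expect_equal(am$values[2, 1], 0.6)
  ps2 <- stokes_image(matrix(1, 2, 2), S3 = matrix(c(1, 0.4, 1, 0.4), 2, 2),
                      mode = "depolarization")
  dm <- depolarization_map(ps2)
  expect_equal(dm$values[1, 1], 0)
  expect_equal(dm$values[2, 1], 0.6)
  # S0 = 0 pixels are invalid, not poisoned
  ps3 <- stokes_image(matrix(c(0, 1), 2, 1), matrix(0.5, 2, 1),
                      matrix(0, 2, 1), mode = "retardance")
  am3 <- retardance_map(ps3)
  expect_false(am3$valid[1, 1])
  expect_true(am3$valid[2, 1])
})

test_that("full noise-free pipeline recovers a retarder's sin(delta)", {
  truth <- uniform_truth(32, 32, delta = pi / 3, theta = 0.8)
  am <- reconstruct_noise_free(scene_to_stokes(truth))
  expect_equal(max(abs(am$values - sin(pi / 3))), 0, tolerance = 1e-6)
})

test_that("maps are invariant to global intensity scaling", {
  truth <- uniform_truth(32, 32, delta = 1.1, theta = 0.2, c = 0.7)
  s <- scene_to_stokes(truth)
  for (k in c(0.25, 4)) {
    s2 <- stokes_image(s$S0 * k, s$S1 * k, s$S2 * k, s$S3 * k, mode = "full")
    expect_equal(reconstruct_noise_free(s2)$values,
                 reconstruct_noise_free(s)$values, tolerance = 1e-12)
    expect_equal(reconstruct_noise_free(s2, "depolarization")$values,
                 reconstruct_noise_free(s, "depolarization")$values,
                 tolerance = 1e-12)
  }
})

test_that("shot-noise patch means are unbiased within 3 standard errors", {
  H <- 64; W <- 64
  truth <- uniform_truth(H, W, delta = pi / 5, theta = 0.3)
  s <- scene_to_stokes(truth)
  vals <- numeric(8)
  for (r in 1:8) {
    mos <- simulate_dofp_mosaic(s, exposure_scale = 2000,
                                noise = list(shot = TRUE, read_sd = 0),
                                bitdepth = 12L, seed = 100 + r)
    am <- retardance_map(partial_stokes_linear(demosaic_bilinear(mos)))
    vals[r] <- mean(am$values[17:48, 17:48])   # central 32x32 patch
  }
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - sin(pi / 5)), 3 * se + 1e-4)
})

test_that("exposure mask applies the half-S0 thresholds", {
  S0 <- matrix(c(500, 10, 200, 400), 2, 2)
  ok <- exposure_mask(S0, bitdepth = 8L)
  expect_false(ok[1, 1])   # 250 > 242.25, overexposed
  expect_false(ok[2, 1])   # 5 < 7.65, underexposed
  expect_true(ok[1, 2])
  expect_true(ok[2, 2])
})

test_that("gamma correction is monotone with fixed endpoints", {
  expect_equal(gamma_correct(1), 1)
  expect_equal(gamma_correct(0), 0)
  expect_equal(gamma_correct(0.25), 0.5)
  set.seed(3)
  x <- matrix(runif(100), 10, 10)
  expect_equal(order(gamma_correct(x)), order(x))
  expect_error(gamma_correct(0.5, gamma = 0), "positive")
  expect_error(gamma_correct(2), "normalized")
})

test_that("rendering marks invalid pixels green and never mutates the map", {
  vals <- matrix(c(0, 1, 0.5, 0.2), 2, 2)
  map <- parameter_map(vals, matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  before <- unserialize(serialize(map, NULL))
  img <- render_map(map)
  expect_equal(img[2, 2, ], c(0, 1, 0))
  pal <- grDevices::hcl.colors(256, "Viridis")
  expect_equal(img[1, 1, ], as.numeric(grDevices::col2rgb(pal[1]) / 255))
  expect_equal(img[2, 1, ], as.numeric(grDevices::col2rgb(pal[256]) / 255))
  expect_identical(map, before)
  allbad <- parameter_map(vals, matrix(FALSE, 2, 2))
  img2 <- render_map(allbad)
  expect_true(all(img2[, , 1] == 0 & img2[, , 2] == 1 & img2[, , 3] == 0))
})
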