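test_that("quadratic calibration recovers exact coefficients and edge cases", {
  d <- seq(280, 320, 5)
  co <- c(4.1, -0.016, 2.1e-5)
  intens <- cbind(co[1] + co[2] * d + co[3] * d^2,
                  2 * (co[1] + co[2] * d + co[3] * d^2))
  cal <- fit_height_calibration(intens, d, 300)
  expect_equal(cal$coeffs[1, ], co, tolerance = 1e-10)
  expect_equal(cal$coeffs[2, ], 2 * co, tolerance = 1e-10)
  # constant intensities: correction factor 1 at every distance
  cal_c <- fit_height_calibration(matrix(7, length(d), 1), d, 300)
  eps <- hsicurve:::eval_calibration(cal_c, 300, 1) /
    hsicurve:::eval_calibration(cal_c, c(285, 300, 315), 1)
  expect_equal(eps, rep(1, 3), tolerance = 1e-9)
  expect_error(fit_height_calibration(matrix(1, 2, 1), c(300, 310), 300),
               "3 distinct")
})

test_that("a quadratic captures inverse-square falloff to better than 1 %", {
  d <- seq(280, 320, 2)
  intens <- matrix(1e4 / d^2, ncol = 1)
  cal <- fit_height_calibration(intens, d, 300)
  fitted <- hsicurve:::eval_calibration(cal, d, 1)
  expect_lt(max(abs(fitted - intens[, 1])) / mean(intens), 0.01)
})

test_that("height correction applies the calibrated distance ratio", {
  wl <- c(550, 650)
  cube <- make_test_cube(3, 3, wl, value = 0.4)
  # all pixels at the working distance: output equals input
  cal <- height_calibration(matrix(c(4.1, -0.016, 2.1e-5), 1), 300)
  flat <- height_map(matrix(0, 3, 3))
  expect_equal(height_correct(cube, flat, cal)$values, cube$values,
               tolerance = 1e-12)
  # P(d) = d^2, pixel at 310 mm: eps = 300^2/310^2
  cal2 <- height_calibration(matrix(c(0, 0, 1), 1), 300,
                             distance_range = c(280, 320))
  h <- height_map(matrix(-10, 3, 3))    # distance = 300 - (-10) = 310
  out <- height_correct(cube, h, cal2)
  expect_equal(out$values[2, 2, 1], 0.4 * 300^2 / 310^2, tolerance = 1e-12)
  expect_true("height" %in% out$corrections)
  # out-of-range distances get flagged
  h_far <- height_map(matrix(-50, 3, 3))
  expect_warning(out2 <- height_correct(cube, h_far, cal2), "range")
  expect_false(any(out2$valid))
})

test_that("Lambert correction divides by the incidence cosine", {
  wl <- c(550, 650)
  cube <- make_test_cube(2, 2, wl, value = 0.3)
  cube$corrections <- "height"
  # theta = 0: identity
  expect_equal(lambert_correct(cube, matrix(1, 2, 2))$values, cube$values)
  # 0.3 at 60 degrees -> 0.6
  out <- lambert_correct(cube, matrix(0.5, 2, 2))
  expect_equal(as.numeric(out$values), rep(0.6, 8))
  # pixels below min_cos get masked, values untouched
  ct <- matrix(c(0.5, 0.05, 0.8, 0.9), 2, 2)
  out2 <- lambert_correct(cube, ct, min_cos = 0.1)
  expect_false(out2$valid[2, 1])
  expect_equal(out2$values[2, 1, 1], 0.3)   # masked pixel unaltered
  # provenance enforcement and missing-field error
  raw <- make_test_cube(2, 2, wl)
  expect_error(lambert_correct(raw, matrix(1, 2, 2)), "height")
  expect_error(lambert_correct(cube, NULL), "required")
})

test_that("a pure Lambert artifact is inverted exactly above the cosine cutoff", {
  wl <- seq(500, 560, 20)
  theta <- matrix(seq(0, 80, length.out = 12), 3, 4)
  ct <- cos(theta * pi / 180)
  base <- make_test_cube(3, 4, wl, value = 0.47)
  shaded <- base
  for (l in seq_along(wl)) shaded$values[, , l] <- 0.47 * ct
  shaded$corrections <- "height"
  rec <- lambert_correct(shaded, ct, min_cos = 0.1)
  expect_equal(rec$values[rep(rec$valid, length(wl))],
               base$values[rep(rec$valid, length(wl))], tolerance = 1e-12)
})

test_that("height + Lambert corrections invert the simulated artifacts to 1e-10", {
  spec <- small_hemisphere(npix = 15)
  sc <- generate_scene(spec, fm = get_phantom_model())
  ws <- simulate_white_stack(spec)
  cal <- fit_height_calibration(ws$intensities, ws$distances, 300)
  ct <- cos_incidence(sc$normals)
  corr <- lambert_correct(height_correct(sc$cube, sc$height_true, cal), ct,
                          min_cos = cos(84 * pi / 180))
  sel <- corr$valid
  for (l in c(1, 28, 55)) {
    rel <- abs(corr$values[, , l] - sc$cube_true$values[, , l]) /
      sc$cube_true$values[, , l]
    expect_lt(max(rel[sel]), 1e-10)
  }
})

test_that("corrections commute with spectral binning for flat artifact fields", {
  wl <- seq(500, 550, 10)
  cube <- make_test_cube(4, 4, wl, value = 0.5)
  cube$values <- cube$values * array(runif(16 * 6, 0.9, 1.1), c(4, 4, 6))
  cube$corrections <- "height"
  ct <- matrix(runif(16, 0.5, 1), 4, 4)
  a <- bin_cube(lambert_correct(cube, ct), 1, 2)
  b <- lambert_correct(bin_cube(cube, 1, 2), ct)
  b$corrections <- a$corrections
  expect_equal(a$values, b$values, tolerance = 1e-12)
})
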