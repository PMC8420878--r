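test_that("a fit initialized at the solution stays there", {
  fm <- get_phantom_model()
  truth <- c(3.7, 1.6)
  meas <- fm$forward(truth)
  f <- fit_spectrum(meas, fm, fit_config(), init = truth)
  expect_true(f$converged)
  expect_lte(f$n_iter, 3)
  expect_equal(unname(f$params), truth, tolerance = 1e-8)
  expect_lt(f$residual_ss, 1e-20)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("noiseless phantom spectra are recovered within 1 percent", {
  fm <- get_phantom_model()
  cfg <- fit_config(n_starts = 300, n_polish = 8, seed = 3)
  for (tr in list(c(3.7, 1.6), c(33.9, 1.6), c(3.5, 7.1))) {
    meas <- fm$forward(tr)
    ms <- multistart_init(meas, fm, cfg)
    f <- fit_spectrum(meas, fm, cfg, init = ms$init)
    expect_lt(max(abs((unname(f$params) - tr) / tr)), 0.01)
  }
})

test_that("noiseless skin spectra identify all six free parameters within 1 percent", {
  fm <- get_skin_model()
  set.seed(14)
  b <- skin_bounds()
  for (i in 1:3) {
    tr <- b$lower + runif(6, 0.25, 0.75) * (b$upper - b$lower)
    meas <- fm$forward(tr)
    f <- fit_spectrum(meas, fm, fit_config(), init = (b$lower + b$upper) / 2)
    expect_lt(max(abs((unname(f$params) - tr) / tr)), 0.01)
  }
})

test_that("uncorrected cosine shading biases the fitted absorber upward", {
  fm <- get_phantom_model()
  truth <- c(3.7, 1.6)
  meas <- fm$forward(truth) * 0.5      # cos(60 deg) shading, no correction
  ms <- multistart_init(meas, fm, fit_config(n_starts = 200, n_polish = 6,
                                             seed = 5))
  f <- fit_spectrum(meas, fm, fit_config(), init = ms$init)
  expect_gt(unname(f$params["cabs_pct"]), truth[1])
})

test_that("multi-start initialization is seeded, deterministic and degenerates to one draw", {
  fm <- get_phantom_model()
  meas <- fm$forward(c(13.3, 5.2))
  cfg <- fit_config(n_starts = 50, n_polish = 4, seed = 9)
  a <- multistart_init(meas, fm, cfg)
  b <- multistart_init(meas, fm, cfg)
  expect_identical(a$init, b$init)
  # n_starts = 1: equals the single seeded draw's polished fit
  cfg1 <- fit_config(n_starts = 1, n_polish = 1, seed = 9)
  one <- multistart_init(meas, fm, cfg1)
  draw <- withr::with_seed(9, matrix(runif(2), ncol = 2))
  p0 <- fm$lower + draw[1, ] * (fm$upper - fm$lower)
  ref <- fit_spectrum(meas, fm, cfg1, init = p0)
  expect_equal(one$init, ref$params, tolerance = 1e-12)
})

test_that("recovery degrades gracefully under 1 percent multiplicative noise", {
  fm <- get_phantom_model()
  truth <- c(3.7, 1.6)
  clean <- fm$forward(truth)
  errs <- withr::with_seed(21, {
    sapply(1:12, function(i) {
      meas <- clean * (1 + rnorm(length(clean), 0, 0.01))
      f <- fit_spectrum(meas, fm, fit_config(), init = truth * c(1.5, 0.7))
      max(abs((unname(f$params) - truth) / truth))
    })
  })
  expect_lt(stats::median(errs), 0.1)
})

test_that("spectra generated outside the bounds land on the boundary, flagged", {
  fm <- get_phantom_model()
  # absorber far beyond the upper bound of 45 %
  slab <- build_slab("phantom", phantom_params(60, 1.6), fm$lambda_nm)
  meas <- forward_spectrum(slab)$r_total
  f <- fit_spectrum(meas, fm, fit_config(), init = c(40, 2))
  expect_equal(unname(f$params["cabs_pct"]), 45)
  expect_true(f$at_bound[1])
})

test_that("fit_cube maps a homogeneous artifact-free scene to a flat map", {
  fm <- get_phantom_model()
  spec <- small_hemisphere(npix = 7, artifacts = list(lambert = FALSE,
                                                      height = FALSE))
  sc <- generate_scene(spec, fm = fm)
  cfg <- fit_config(bin_factors = c(1, 1), n_starts = 60, n_polish = 4,
                    seed = 2)
  map <- fit_cube(sc$cube, fm, cfg,
                  init_region = list(rows = 3:5, cols = 3:5))
  px <- tidy(map)
  expect_true(all(px$converged))
  expect_lt(max(abs(px$cabs_pct - 3.7) / 3.7), 0.01)
  expect_lt(max(abs(px$csc_pct - 1.6) / 1.6), 0.01)
  g <- glance(map)
  expect_equal(g$n_pixels, sum(sc$cube$valid))
  # determinism: identical seeds and inputs give identical maps
  map2 <- fit_cube(sc$cube, fm, cfg, init_region = list(rows = 3:5, cols = 3:5))
  expect_identical(tidy(map), tidy(map2))
})

test_that("radial averages summarize maps with their dispersion", {
  # radially symmetric field: per-annulus sd vanishes; profile matches f(r)
  n <- 41
  cx <- (n + 1) / 2
  r <- sqrt(((row(matrix(0, n, n)) - cx))^2 + ((col(matrix(0, n, n)) - cx))^2)
  m <- 2 + 0.1 * r
  prof <- radial_average(m, bin_width_mm = 1)
  inner <- prof[prof$n > 0 & prof$radius_mm < 15, ]
  expect_true(all(inner$sd < 0.06))
  expect_equal(inner$mean, 2 + 0.1 * inner$radius_mm, tolerance = 0.05)
  # constant map: flat profile at the constant
  profc <- radial_average(matrix(7, 21, 21), bin_width_mm = 2)
  expect_true(all(abs(profc$mean[profc$n > 0] - 7) < 1e-12))
  expect_error(radial_average(m, center = c(100, 1)), "inside")
})

test_that("max_valid_angle finds the first tolerance violation", {
  # constructed profile: accurate to 30 degrees, then a 10 percent step
  prof <- tibble::tibble(radius_mm = 1:10,
                         mean = c(rep(1, 6), rep(1.1, 4)),
                         sd = 0, n = 5,
                         theta_deg = seq(5, 50, 5))
  expect_equal(max_valid_angle(prof, central_value = 1), 30)
  # exactly constant profile: the full angular range is valid
  profc <- prof; profc$mean <- 1
  expect_equal(max_valid_angle(profc, central_value = 1), 50)
  # first annulus already off: zero
  prof0 <- prof; prof0$mean <- 2
  expect_equal(max_valid_angle(prof0, central_value = 1), 0)
})
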