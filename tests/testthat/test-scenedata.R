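test_that("normalization maps raw counts to reflectance per the white/dark frames", {
  d <- c(3, 4, 2)
  dark <- matrix(100, d[1], d[2])
  white <- array(1100, d)
  # R = D everywhere -> I = 0; R = W -> I = 1
  sc0 <- raw_scan(array(100, d), dark, white, c(500, 600))
  expect_equal(normalize_reflectance(sc0)$values, array(0, d))
  sc1 <- raw_scan(white, dark, white, c(500, 600))
  expect_equal(normalize_reflectance(sc1)$values, array(1, d))
  # single-voxel arithmetic: (600 - 100) / (1100 - 100) = 0.5
  raw <- array(100, d); raw[2, 3, 1] <- 600
  cube <- normalize_reflectance(raw_scan(raw, dark, white, c(500, 600)))
  expect_equal(cube$values[2, 3, 1], 0.5)
})

test_that("degenerate white frames flag pixels invalid instead of clipping", {
  d <- c(2, 2, 1)
  white <- array(1100, d); white[1, 1, 1] <- 100   # white == dark
  sc <- raw_scan(array(600, d), matrix(100, 2, 2), white, 550)
  expect_warning(cube <- normalize_reflectance(sc), "invalid")
  expect_false(cube$valid[1, 1])
  expect_true(cube$valid[2, 2])
  expect_true(is.na(cube$values[1, 1, 1]))
})

test_that("frame shape mismatches and bad wavelength axes are rejected", {
  expect_error(raw_scan(array(1, c(2, 2, 2)), matrix(0, 3, 2),
                        array(2, c(2, 2, 2)), c(1, 2)), "grid")
  expect_error(raw_scan(array(1, c(2, 2, 2)), matrix(0, 2, 2),
                        array(2, c(2, 2, 2)), c(2, 1)), "increasing")
  expect_error(reflectance_cube(array(1, c(2, 2, 3)), c(1, 2)), "bands")
})

test_that("bin_cube computes block means and rescales the axes", {
  # 2x2 block {1,2,3,4} -> 2.5
  v <- array(0, c(2, 2, 1)); v[, , 1] <- matrix(1:4, 2, 2)
  cube <- reflectance_cube(v, 550, pixel_pitch = c(1, 1))
  b <- bin_cube(cube, 2, 1)
  expect_equal(dim(b$values), c(1L, 1L, 1L))
  expect_equal(b$values[1, 1, 1], 2.5)
  expect_equal(b$pixel_pitch, c(2, 2))
  # constant cube stays constant; factors (1,1) are the identity
  cc <- make_test_cube(6, 9, seq(500, 550, 10), value = 0.31)
  expect_equal(unique(as.numeric(bin_cube(cc, 3, 2)$values)), 0.31)
  expect_equal(bin_cube(cc, 1, 1)$values, cc$values)
  expect_error(bin_cube(cc, 7, 1), "larger")
})

test_that("binning conserves the global mean over fully tiled regions", {
  set.seed(41)
  v <- array(runif(8 * 6 * 4), c(8, 6, 4))
  cube <- reflectance_cube(v, seq(500, 530, 10))
  b <- bin_cube(cube, 2, 2)
  expect_equal(mean(b$values), mean(v), tolerance = 1e-12)
  # wavelength axis becomes block means
  expect_equal(b$wavelengths, c(505, 525))
})

test_that("ENVI round trip is bit-exact and interleaves agree", {
  set.seed(7)
  cube <- reflectance_cube(array(rnorm(5 * 4 * 3), c(5, 4, 3)),
                           c(500, 600, 700), pixel_pitch = c(0.4, 0.5),
                           working_distance = 310)
  tmp <- withr::local_tempdir()
  for (il in c("bsq", "bil", "bip")) {
    p <- file.path(tmp, il)
    write_cube(cube, p, "envi", interleave = il)
    back <- read_cube(p)
    expect_identical(back$values, cube$values)
    expect_identical(back$wavelengths, cube$wavelengths)
    expect_equal(back$pixel_pitch, cube$pixel_pitch)
    expect_equal(back$working_distance, cube$working_distance)
  }
})

test_that("TIFF dialect round trips within float precision and keeps orientation", {
  set.seed(8)
  v <- array(runif(6 * 5 * 2), c(6, 5, 2))
  v[1, 1, ] <- c(0.111, 0.222)   # marker at the first scan line's first sample
  cube <- reflectance_cube(v, c(550, 650))
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "cube")
  write_cube(cube, p, "tiff")
  back <- read_cube(p, "tiff")
  expect_equal(back$values, cube$values, tolerance = 1e-6)
  expect_equal(back$values[1, 1, ], c(0.111, 0.222), tolerance = 1e-6)
  expect_equal(back$wavelengths, cube$wavelengths)
})

test_that("missing spectral metadata is an error", {
  tmp <- withr::local_tempdir()
  cube <- make_test_cube()
  p <- file.path(tmp, "x")
  write_cube(cube, p, "envi")
  hdr <- readLines(paste0(p, ".hdr"))
  writeLines(hdr[!grepl("^wavelength", hdr)], paste0(p, ".hdr"))
  expect_error(read_cube(p), "wavelength")
  p2 <- file.path(tmp, "y")
  write_cube(cube, p2, "tiff")
  file.remove(paste0(p2, ".json"))
  expect_error(read_cube(p2, "tiff"), "sidecar|axis")
})

test_that("height maps round trip through float TIFF with invalid points", {
  z <- matrix(rnorm(20), 4, 5)
  z[2, 3] <- NA
  h <- height_map(z)
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "h.tif")
  write_height(h, p)
  back <- read_height(p)
  expect_equal(back$z[-7], z[-7], tolerance = 1e-5)
  expect_false(back$valid[2, 3])
})

test_that("normalization is consistent with a trivial calibration", {
  # D = 0, W = 1 returns the raw values unchanged
  d <- c(3, 3, 2)
  raw <- array(runif(prod(d)), d)
  sc <- raw_scan(raw, matrix(0, 3, 3), array(1, d), c(500, 600))
  expect_equal(normalize_reflectance(sc)$values, raw)
})
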