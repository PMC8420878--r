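test_that("triangulation reproduces the closed-form height relations", {
  geom <- profilometer_geometry(L = 100, alpha = 26, beta = 26, f = 17)
  # zero displacement: dz = L / (tan b + tan a)
  h0 <- triangulate_height(matrix(0, 2, 2), geom)
  expect_equal(h0$z[1, 1], 100 / (2 * tan(26 * pi / 180)), tolerance = 1e-12)
  expect_equal(h0$z[1, 1], 102.51528, tolerance = 1e-6)
  # displacement cancelling the incidence term: dz = L / tan b
  dy_star <- 17 * tan(26 * pi / 180)
  h1 <- triangulate_height(matrix(dy_star, 1, 1), geom)
  expect_equal(h1$z[1, 1], 100 / tan(26 * pi / 180), tolerance = 1e-9)
  # NA displacements invalidate points
  h2 <- triangulate_height(matrix(c(0, NA), 1, 2), geom)
  expect_false(h2$valid[1, 2])
})

test_that("triangulation is monotone in the displacement over the valid branch", {
  geom <- profilometer_geometry(L = 100, alpha = 26, beta = 26, f = 17)
  dy <- seq(-5, 5, length.out = 101)
  z <- triangulate_height(matrix(dy, 1), geom)$z
  expect_true(all(diff(as.numeric(z)) > 0) || all(diff(as.numeric(z)) < 0))
})

test_that("impossible ray geometry invalidates points with a warning", {
  geom <- profilometer_geometry(L = 100, alpha = 80, beta = 5, f = 17)
  # large negative dy drives alpha - atan(dy/f) past the pole
  expect_warning(h <- triangulate_height(matrix(-60, 1, 1), geom),
                 "invalidated")
  expect_false(h$valid[1, 1])
})

test_that("laplace_fill solves the harmonic interpolation problem", {
  # planes are harmonic: filling reproduces them exactly
  nr <- 12; nc <- 14
  z <- outer(seq_len(nr), seq_len(nc), function(i, j) 0.3 * i - 0.2 * j + 5)
  zh <- z
  zh[4:7, 5:9] <- NA
  filled <- laplace_fill(height_map(zh))
  expect_equal(filled$z, z, tolerance = 1e-9)
  expect_true(all(filled$valid))
  # single missing pixel with 4 known neighbours {1,2,3,4} -> 2.5
  z1 <- matrix(0, 3, 3)
  z1[1, 2] <- 1; z1[3, 2] <- 2; z1[2, 1] <- 3; z1[2, 3] <- 4
  z1[2, 2] <- NA
  expect_equal(laplace_fill(height_map(z1))$z[2, 2], 2.5)
  # no missing pixels: identity
  full <- height_map(matrix(rnorm(12), 3, 4))
  expect_identical(laplace_fill(full)$z, full$z)
  # nothing to interpolate from
  expect_error(laplace_fill(height_map(matrix(NA_real_, 2, 2))), "valid")
})

test_that("filled values obey the discrete maximum principle", {
  set.seed(99)
  for (rep in 1:5) {
    z <- matrix(rnorm(15 * 15), 15, 15)
    zh <- z
    hole <- cbind(sample(3:13, 20, TRUE), sample(3:13, 20, TRUE))
    zh[hole] <- NA
    filled <- laplace_fill(height_map(zh))
    known <- z[!is.na(zh)]
    expect_true(all(filled$z >= min(known) - 1e-10))
    expect_true(all(filled$z <= max(known) + 1e-10))
  }
})

test_that("normals and incidence angles match analytic geometry", {
  # flat surface: n = (0,0,1), theta = 0
  nf <- compute_normals(height_map(matrix(1.5, 8, 8)), pixel_pitch = 0.5)
  expect_equal(nf$n[, , 3], matrix(1, 8, 8))
  expect_equal(max(nf$theta), 0)
  # unit norm everywhere
  nrm <- sqrt(nf$n[, , 1]^2 + nf$n[, , 2]^2 + nf$n[, , 3]^2)
  expect_equal(nrm, matrix(1, 8, 8), tolerance = 1e-9)
  # 45-degree plane
  pitch <- 0.2
  z45 <- outer(rep(1, 20), seq_len(20)) * pitch   # dz/dx = 1
  nf45 <- compute_normals(height_map(z45), pixel_pitch = pitch)
  expect_true(all(abs(nf45$theta[, 2:19] - 45) < 0.5))
  # hemisphere: theta = arcsin(r / R) within 1 degree for r/R <= 0.9
  R <- 20; pitch <- 0.25; n <- 121; cx <- 61
  x <- (col(matrix(0, n, n)) - cx) * pitch
  y <- (row(matrix(0, n, n)) - cx) * pitch
  r <- sqrt(x^2 + y^2)
  z <- ifelse(r < R, sqrt(pmax(R^2 - r^2, 0)), 0)
  nf_h <- compute_normals(height_map(z), pixel_pitch = pitch)
  inside <- r / R <= 0.9 & r / R >= 0.05
  theta_true <- asin(pmin(r / R, 1)) * 180 / pi
  expect_lt(max(abs(nf_h$theta[inside] - theta_true[inside])), 1)
})

test_that("cos_incidence is the dot product with the illumination direction", {
  n <- array(0, c(1, 3, 3))
  n[1, 1, ] <- c(0, 0, 1)                        # parallel
  n[1, 2, ] <- c(1, 0, 0)                        # orthogonal
  n[1, 3, ] <- c(sin(pi / 3), 0, cos(pi / 3))    # 60 degrees
  nf <- normal_field(n)
  ct <- cos_incidence(nf, c(0, 0, 1))
  expect_equal(as.numeric(ct), c(1, 0, 0.5), tolerance = 1e-12)
})

test_that("affine registration resamples height maps onto the cube grid", {
  z <- outer(1:10, 1:12, function(i, j) 0.5 * i + 0.25 * j)
  h <- height_map(z)
  # identity transform: unchanged
  r0 <- register_height(h, c(10, 12))
  expect_equal(r0$z, z)
  expect_true(all(r0$valid))
  # integer translation by (2, 3): shifted values where defined
  r1 <- register_height(h, c(10, 12), t = c(2, 3))
  expect_equal(r1$z[1, 1], z[3, 4])
  expect_false(r1$valid[10, 12])   # maps outside the source grid
  # half-pixel shift: bilinear mean of neighbours on a plane is exact
  r2 <- register_height(h, c(10, 12), t = c(0.5, 0))
  expect_equal(r2$z[4, 5], (z[4, 5] + z[5, 5]) / 2)
  # invalid source points poison their bilinear support
  zh <- z; zh[5, 6] <- NA
  r3 <- register_height(height_map(zh), c(10, 12), t = c(0.5, 0))
  expect_false(r3$valid[5, 6])
})
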