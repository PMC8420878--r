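test_that("quadrature includes the normal cone and normalizes weights", {
  for (n_rel in c(1, 1.4)) {
    q <- ad_quadrature(20, n_rel)
    expect_equal(sum(q$w), 1, tolerance = 1e-12)
    expect_equal(max(q$mu), 1, tolerance = 1e-12)
    expect_true(all(diff(q$mu) > 0))
    expect_true(all(q$w > 0))
  }
  # mismatched slab: cones straddle the critical cosine
  q <- ad_quadrature(20, 1.4)
  mu_c <- sqrt(1 - 1 / 1.4^2)
  expect_equal(sum(q$mu < mu_c), 10)
})

test_that("redistribution matrices are normalized and forward-peaked for g > 0", {
  q <- ad_quadrature(20, 1)
  h0 <- hg_redistribution(0, q)
  # isotropic: all entries equal after normalization
  expect_lt(diff(range(h0$hpp)), 1e-12)
  expect_equal(h0$hpp[1, 1], h0$hpm[1, 1], tolerance = 1e-12)
  h <- hg_redistribution(0.82, q)
  rs <- (h$hpp + h$hpm) %*% (q$w / 2)
  expect_equal(as.numeric(rs), rep(1, 20), tolerance = 1e-12)
  # forward peaking: same-hemisphere near-diagonal mass exceeds isotropic
  expect_gt(mean(diag(h$hpp)), mean(diag(h0$hpp)))
  expect_gt(h$hpp[20, 20], h$hpm[20, 20])
  expect_error(hg_redistribution(1, q), "g")
})

test_that("layer operators reduce to Beer-Lambert without scattering", {
  q <- ad_quadrature(20, 1)
  ops <- layer_rt(mua = 1, mus = 0, g = 0, thickness_cm = 1, scheme = q)
  expect_equal(max(abs(ops$R)), 0)
  expect_equal(diag(ops$T), exp(-1 / q$mu), tolerance = 1e-9)
  expect_equal(max(abs(ops$T - diag(diag(ops$T)))), 0)
  # zero thickness: identity transmission
  ops0 <- layer_rt(0.5, 10, 0.8, 0, q)
  expect_equal(ops0$T, diag(20))
  expect_equal(max(abs(ops0$R)), 0)
})

test_that("modal and doubling layer solutions agree", {
  q <- ad_quadrature(20, 1.4)
  for (cs in list(c(0.9, 5, 0.82), c(0.5, 0.3, 0), c(0.998, 300, 0.95))) {
    h <- hg_redistribution(cs[3], q)
    a <- hsicurve:::cpp_layer_ops(q$mu, q$w, h$hpp, h$hpm, cs[1], cs[2],
                                  "doubling")
    b <- hsicurve:::cpp_layer_ops(q$mu, q$w, h$hpp, h$hpm, cs[1], cs[2],
                                  "modal")
    expect_lt(max(abs(a$R - b$R)), 1e-6)
    expect_lt(max(abs(a$T - b$T)), 1e-6)
  }
})

test_that("layer operators satisfy flux reciprocity", {
  q <- ad_quadrature(20, 1)
  ops <- layer_rt(0.3, 20, 0.82, 0.5, q)
  # radiance-basis reflection R_ij / (2 mu_i w_i) is symmetric
  s <- ops$R / (2 * q$mu * q$w)
  expect_equal(s, t(s), tolerance = 1e-8)
  st <- ops$T / (2 * q$mu * q$w)
  expect_equal(st, t(st), tolerance = 1e-8)
})

test_that("energy is conserved for conservative slabs and accounted with boundaries", {
  # conservative isotropic slab, matched boundaries
  r <- ad_rt(list(list(mua = 0, mus = 1, g = 0, thickness_cm = 10)), 1)
  expect_equal(r$r_total + r$t_total, 1, tolerance = 1e-6)
  r2 <- ad_rt(list(list(mua = 0, mus = 1, g = 0.82, thickness_cm = 10)), 1)
  expect_equal(r2$r_total + r2$t_total, 1, tolerance = 1e-6)
  # semi-infinite conservative slab: everything reflects
  r3 <- ad_rt(list(list(mua = 0, mus = 10, g = 0, thickness_cm = 100)), 1)
  expect_equal(r3$r_total, 1, tolerance = 5e-3)
  # index-matched vacuum slab
  r4 <- ad_rt(list(list(mua = 0, mus = 0, g = 0, thickness_cm = 1)), 1)
  expect_equal(r4$r_total, 0, tolerance = 1e-12)
  expect_equal(r4$t_total, 1, tolerance = 1e-12)
  # absorbing mismatched slab: full bookkeeping closes
  r5 <- ad_rt(list(list(mua = 0.5, mus = 20, g = 0.82, thickness_cm = 2)), 1.4)
  expect_equal(r5$r_total + r5$t_total + r5$a_total + r5$r_specular, 1,
               tolerance = 1e-9)
})

test_that("energy closes within 1e-6 across random in-range parameter draws", {
  set.seed(5)
  for (i in 1:10) {
    mua <- runif(1, 0.1, 1.1)
    musp <- runif(1, 8, 40)
    g <- sample(c(0, 0.82), 1)
    n <- sample(c(1, 1.4), 1)
    r <- ad_rt(list(list(mua = mua, mus = musp / (1 - g), g = g,
                         thickness_cm = 2)), n)
    expect_equal(r$r_total + r$t_total + r$a_total + r$r_specular, 1,
                 tolerance = 1e-6)
    expect_true(r$r_total >= 0 && r$r_total <= 1)
    expect_true(r$a_total >= 0 && r$a_total <= 1)
  }
})

test_that("adding-doubling matches the Monte-Carlo photon oracle", {
  set.seed(31)
  cases <- list(c(0.1, 8, 0.82, 1.4), c(1.1, 40, 0.82, 1.4),
                c(0.5, 20, 0, 1.0), c(0.4, 15, 0.82, 1.0))
  for (cs in cases) {
    layer <- list(mua = cs[1], mus = cs[2] / (1 - cs[3]), g = cs[3],
                  thickness_cm = 2, n = cs[4])
    r_ad <- ad_rt(list(layer), n_slab = cs[4])
    r_mc <- mc_slab(list(layer), n_photons = 1e5, seed = 123)
    expect_lt(abs(r_ad$r_total - r_mc$R), max(0.003, 3 * r_mc$R_se))
  }
})

test_that("Monte-Carlo oracle is deterministic for a fixed seed", {
  layer <- list(mua = 0.5, mus = 20, g = 0.82, thickness_cm = 2, n = 1.4)
  a <- mc_slab(list(layer), n_photons = 1e4, seed = 77)
  b <- mc_slab(list(layer), n_photons = 1e4, seed = 77)
  expect_identical(a, b)
})

test_that("reflectance converges in the number of cones", {
  for (cs in list(c(0.3, 15, 0.82, 1.4), c(0.8, 30, 0, 1.0))) {
    layers <- list(list(mua = cs[1], mus = cs[2] / (1 - cs[3]), g = cs[3],
                        thickness_cm = 2))
    r20 <- ad_rt(layers, n_slab = cs[4], M = 20)
    r40 <- ad_rt(layers, n_slab = cs[4], M = 40)
    expect_lt(abs(r20$r_total - r40$r_total), 5e-4)
  }
})

test_that("forward spectra are monotone in absorber content and smooth", {
  fm <- get_phantom_model()
  r_lo <- fm$forward(c(5, 3))
  r_mid <- fm$forward(c(15, 3))
  r_hi <- fm$forward(c(30, 3))
  expect_true(all(r_mid < r_lo))
  expect_true(all(r_hi < r_mid))
  # no quadrature-induced jumps: spectrally flat properties (constant index)
  # must give a flat spectrum, and adding slow dispersion only a slow drift
  grid <- default_grid()
  flat <- structure(list(layers = list(layer_properties(grid, 0.5, 20, 0.82,
                                                        1.4, 2)),
                         lambda_nm = grid, n_outside = 1, model = "phantom"),
                    class = "slab_model")
  rf <- forward_spectrum(flat)$r_total
  expect_lt(max(abs(diff(rf))), 1e-10)
  disp <- structure(list(layers = list(layer_properties(grid, 0.5, 20, 0.82,
                                                        siliglass_refractive_index(grid),
                                                        2)),
                         lambda_nm = grid, n_outside = 1, model = "phantom"),
                    class = "slab_model")
  rd <- forward_spectrum(disp)$r_total
  # adjacent-step changes bounded by the physical dispersion scale
  expect_lt(max(abs(diff(rd))), 5e-4)
  # the slab-model route and the fitting-model route agree
  slab <- build_slab("phantom", phantom_params(3.7, 1.6), default_grid())
  fs <- forward_spectrum(slab)
  expect_equal(fs$r_total, fm$forward(c(3.7, 1.6)), tolerance = 1e-10)
})
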