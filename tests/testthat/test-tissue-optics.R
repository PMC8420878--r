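test_that("phantom mass relations follow the recipe algebra", {
  # zero concentrations: everything is part A and part B
  m0 <- phantom_masses(0, 0, 50)
  expect_equal(unlist(m0), c(mabs_g = 0, msc_g = 0, mB_g = 50))
  # mabs = 2 * 0.037 * 50 / (1 - 2 * 0.037) = 3.7 / 0.926
  m1 <- phantom_masses(0.037, 0, 50)
  expect_equal(m1$mabs_g, 3.7 / 0.926, tolerance = 1e-12)
  # msc = 2 * 0.016 * 50 = 1.6; mB = 50 - 1.6 = 48.4
  m2 <- phantom_masses(0, 0.016, 50)
  expect_equal(m2$msc_g, 1.6)
  expect_equal(m2$mB_g, 48.4)
  # wall-loss option increases part B by 1 g
  m3 <- phantom_masses(0, 0.016, 50, wall_loss = TRUE)
  expect_equal(m3$mB_g, 49.4)
  expect_error(phantom_masses(0.5, 0, 50), "pole")
})

test_that("silicone Sellmeier dispersion matches direct evaluation", {
  # at the reference wavelength lr = 1
  expect_equal(siliglass_refractive_index(436.4),
               sqrt(1 + 0.95007197 / (1 - 0.05943376)), tolerance = 1e-12)
  expect_equal(siliglass_refractive_index(436.4), 1.41779, tolerance = 1e-5)
  # long-wavelength limit sqrt(1.95007197)
  expect_equal(siliglass_refractive_index(1e9), sqrt(1.95007197),
               tolerance = 1e-6)
  # normal dispersion: strictly decreasing above the reference
  n <- siliglass_refractive_index(seq(440, 900, 20))
  expect_true(all(diff(n) < 0))
})

test_that("phantom absorption combines medium and pigment linearly", {
  tabs <- phantom_tables()
  grid <- default_grid()
  # no pigment: pure medium
  expect_equal(phantom_mua(phantom_params(0, 0), tabs, grid),
               resample_table(tabs$medium, grid))
  # dilution constant cancels at cabs = 0.13246 (fractional) when medium = 0
  tabs0 <- tabs
  tabs0$medium$value <- 0 * tabs0$medium$value
  mua <- phantom_mua(list(cabs_pct = 13.246), tabs0, grid)
  expect_equal(mua, (1) * resample_table(tabs$pigment, grid) * 1,
               tolerance = 1e-9)
  # linear superposition in cabs (fixed medium contribution subtracted)
  m1 <- phantom_mua(list(cabs_pct = 5), tabs0, grid)
  m2 <- phantom_mua(list(cabs_pct = 10), tabs0, grid)
  expect_equal(2 * m1, m2, tolerance = 1e-12)
  expect_error(phantom_mua(phantom_params(5, 1), tabs, c(300, 500)),
               "coverage")
})

test_that("Mie code agrees with the Rayleigh limit and energy balance", {
  m <- 1.59 / 1.41
  r <- mie_sphere(0.05 * 0.55 / (2 * pi * 1.41) * 1000 / 1000, 550, 1.59, 1.41)
  # choose radius so x = 0.05 exactly
  x_target <- 0.05
  radius <- x_target * (550 / 1000) / (2 * pi * 1.41)
  r <- mie_sphere(radius, 550, 1.59, 1.41)
  expect_equal(r$x, x_target, tolerance = 1e-12)
  expect_equal(r$qsca, rayleigh_qsca(x_target, m), tolerance = 0.01)
  # non-absorbing sphere: qabs = 0, qext = qsca
  r7 <- mie_sphere(7, 600, 1.46, 1.41)
  expect_equal(r7$qabs, 0, tolerance = 1e-10)
  expect_equal(r7$qext, r7$qsca, tolerance = 1e-10)
})

test_that("Mie code matches an independent Bessel-function implementation", {
  cases <- list(c(7, 600, 1.46, 1.41), c(2, 550, 1.59, 1.41),
                c(0.5, 430, 1.5, 1.0), c(15, 700, 1.59, 1.41))
  # both implementations accumulate rounding beyond size parameter ~150
  tols <- c(1e-6, 1e-6, 1e-6, 5e-6)
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    got <- mie_sphere(cs[1], cs[2], cs[3], cs[4])
    x <- 2 * pi * cs[1] * cs[4] / (cs[2] / 1000)
    ora <- mie_oracle(x, cs[3] / cs[4])
    expect_equal(got$qsca, ora$qsca, tolerance = tols[k])
    expect_equal(got$qext, ora$qext, tolerance = tols[k])
    expect_equal(got$g, ora$g, tolerance = tols[k])
  }
})

test_that("polydisperse scattering reduces correctly and weights linearly", {
  lam <- c(500, 600)
  # single radius: mus = 3 phi Qsca / (4 r)
  d1 <- sphere_distribution(5, 0.4)
  sc <- distribution_scattering(d1, lam, n_sphere = 1.59)
  q <- mie_sphere(5, lam, 1.59, siliglass_refractive_index(lam))
  expect_equal(sc$mus_cal, 3 * 0.4 * q$qsca / (4 * 5e-4), tolerance = 1e-9)
  expect_equal(sc$g, q$g, tolerance = 1e-12)
  # doubling the volume fractions doubles mus, leaves g unchanged
  d2 <- sphere_distribution(c(2, 8), c(0.1, 0.3))
  d2x <- sphere_distribution(c(2, 8), 2 * c(0.1, 0.3))
  s2 <- distribution_scattering(d2, lam)
  s2x <- distribution_scattering(d2x, lam)
  expect_equal(s2x$mus_cal, 2 * s2$mus_cal, tolerance = 1e-12)
  expect_equal(s2x$g, s2$g, tolerance = 1e-12)
  # weighted g lies within the single-sphere range
  g_singles <- sapply(c(2, 8), function(r)
    mie_sphere(r, 550, 1.59, siliglass_refractive_index(550))$g)
  gd <- distribution_scattering(d2, 550)$g
  expect_gte(gd, min(g_singles)); expect_lte(gd, max(g_singles))
  # forward-peaked regime at the large-sphere end
  d7 <- distribution_scattering(sphere_distribution(7, 1), 550)
  expect_gt(d7$g, 0.9); expect_lt(d7$g, 1)
  expect_error(sphere_distribution(numeric(0), numeric(0)), "empty")
})

test_that("epidermis and melanin absorption follow the power law", {
  grid <- default_grid()
  expect_equal(epidermis_mua(0, grid), rep(0.25, length(grid)))
  expect_equal(melanin_mua(500), 6.6e11 * 500^-3.33, tolerance = 1e-12)
  expect_equal(melanin_mua(500), 678, tolerance = 3e-3)
  expect_true(all(diff(melanin_mua(grid)) < 0))
})

test_that("dermis absorption assembles the chromophore terms", {
  tabs <- chromophore_tables()
  grid <- default_grid()
  zero <- skin_params(fmel = 0, fhb = 0, fhbo2 = 0, fcyt_red = 0,
                      fcyt_ox = 0, a = 30)
  expect_equal(dermis_mua(zero, tabs, grid), rep(0.25, length(grid)))
  only_hb <- skin_params(fhb = 5, fhbo2 = 0, fcyt_red = 0, fcyt_ox = 0)
  expect_equal(dermis_mua(only_hb, tabs, grid) - 0.25,
               0.05 * resample_table(tabs$hb, grid), tolerance = 1e-12)
  # linearity in the blood fractions
  d1 <- dermis_mua(skin_params(fhb = 2, fhbo2 = 1, fcyt_red = 0, fcyt_ox = 0),
                   tabs, grid) - 0.25
  d2 <- dermis_mua(skin_params(fhb = 4, fhbo2 = 2, fcyt_red = 0, fcyt_ox = 0),
                   tabs, grid) - 0.25
  expect_equal(2 * d1, d2, tolerance = 1e-12)
})

test_that("the bundled Hb/HbO2 tables cross at isosbestic wavelengths", {
  tabs <- chromophore_tables()
  grid <- seq(450, 700, 1)
  hb <- resample_table(tabs$hb, grid)
  hbo2 <- resample_table(tabs$hbo2, grid)
  dif <- hb - hbo2
  crossings <- which(diff(sign(dif)) != 0)
  expect_gte(length(crossings), 1)
  # at 50 % saturation both blood terms contribute identically there
  iso <- grid[crossings[1]]
  sat <- skin_params(fhb = 2, fhbo2 = 2, fcyt_red = 0, fcyt_ox = 0)
  term_hb <- 0.02 * resample_table(tabs$hb, iso)
  term_hbo2 <- 0.02 * resample_table(tabs$hbo2, iso)
  expect_equal(term_hb, term_hbo2, tolerance = 0.02 * max(term_hb))
})

test_that("skin scattering ansatz and refractive index evaluate correctly", {
  expect_equal(skin_mus_prime(30, 500), 30)
  expect_equal(skin_mus_prime(30, 650), 30 * 1.3^-1.27, tolerance = 1e-12)
  expect_equal(skin_mus_prime(30, 650), 21.55, tolerance = 0.01)
  grid <- default_grid()
  # similarity relation inside the slab builder: mus = mus' / (1 - 0.82)
  sk <- build_slab("skin", skin_params(a = 25), grid)
  expect_equal(sk$layers[[1]]$mus, skin_mus_prime(25, grid) / 0.18,
               tolerance = 1e-12)
  expect_equal(skin_refractive_index(500),
               1.309 + 4.36e2 / 500^2 + 1.6065e9 / 500^4 -
                 1.12811e14 / 500^6, tolerance = 1e-12)
})

test_that("build_slab assembles the layer stacks with bounded properties", {
  grid <- default_grid()
  ph <- build_slab("phantom", phantom_params(3.7, 1.6), grid)
  expect_length(ph$layers, 1)
  expect_equal(ph$layers[[1]]$thickness_cm, 2)
  # stated phantom absorption band
  expect_true(all(ph$layers[[1]]$mua >= 0.1 - 1e-6))
  expect_true(all(ph$layers[[1]]$mua <= 1.1))
  sk <- build_slab("skin", skin_params(), grid)
  expect_length(sk$layers, 2)
  expect_equal(sk$layers[[1]]$thickness_cm, 0.01)
  expect_equal(sk$layers[[2]]$thickness_cm, 1)
  # all-zero optional absorbers: flat dermis baseline
  sk0 <- build_slab("skin", skin_params(fhb = 0, fhbo2 = 0, fcyt_red = 0,
                                        fcyt_ox = 0), grid)
  expect_equal(sk0$layers[[2]]$mua, rep(0.25, length(grid)))
  # non-negative and finite over the band for in-bound parameters
  set.seed(2)
  b <- skin_bounds()
  for (i in 1:5) {
    p <- runif(6, b$lower, b$upper)
    s <- build_slab("skin", skin_params(p[1], p[2], p[3], p[4], p[5], p[6]),
                    grid)
    for (ly in s$layers) {
      expect_true(all(is.finite(ly$mua)) && all(ly$mua >= 0))
      expect_true(all(is.finite(ly$mus)) && all(ly$mus >= 0))
    }
  }
})

test_that("coated-sphere Mie reduces to the homogeneous limits", {
  # equal core and shell index: exactly the homogeneous sphere
  hom <- mie_sphere(5, 600, 1.5, 1.41)
  coat <- mie_coated_sphere(4, 1, 600, 1.5, 1.5, 1.41)
  expect_equal(coat$qsca, hom$qsca, tolerance = 1e-8)
  expect_equal(coat$g, hom$g, tolerance = 1e-8)
  # vanishing core: homogeneous sphere of the shell index
  shell_only <- mie_sphere(3, 550, 1.59, 1.41)
  tiny_core <- mie_coated_sphere(0.03, 2.97, 550, 1.45, 1.59, 1.41)
  expect_equal(tiny_core$qsca, shell_only$qsca, tolerance = 1e-3)
  # a genuine shell changes the efficiencies
  real_coat <- mie_coated_sphere(4, 1, 600, 1.46, 1.59, 1.41)
  expect_gt(abs(real_coat$qsca - mie_sphere(5, 600, 1.46, 1.41)$qsca), 1e-3)
  # coated mode of the distribution builder is wired through
  d <- sphere_distribution(c(3, 7), c(0.2, 0.2))
  s_hom <- distribution_scattering(d, 550)
  s_coat <- distribution_scattering(d, 550, n_sphere = 1.46, shell_um = 1,
                                    n_shell = 1.59)
  expect_false(isTRUE(all.equal(s_hom$mus_cal, s_coat$mus_cal)))
  expect_error(distribution_scattering(d, 550, shell_um = 1), "n_shell")
})
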