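#' Synthetic scene specification
#'
#' Describes a synthetic imaging scene: a geometry (hemisphere on a base
#' plane, tilted plane, or a finger-like cylinder), a homogeneous material
#' (phantom or skin parameters), the artifact switches (Lambert cosine
#' shading, distance falloff, additive interreflection), and the noise model
#' (multiplicative Gaussian on the cube, Gaussian height noise, optional
#' laser-shadow holes). The default hemisphere radius is 15 mm, matching the
#' hemispherical phantom moulds the pipeline emulates.
#'
#' @param geometry list: `type` one of `"hemisphere"`, `"plane"`,
#'   `"cylinder"`; `radius_mm` (hemisphere/cylinder, default 15);
#'   `tilt_deg` (plane); `npix` grid size (default 41); `pitch_mm` pixel
#'   pitch (default 0.8).
#' @param material a [phantom_params()] or [skin_params()].
#' @param model `"phantom"` or `"skin"` (default guessed from `material`).
#' @param lambda_nm wavelength grid of the generated cube.
#' @param artifacts list: `lambert` (TRUE), `height` (TRUE),
#'   `interreflection` additive ambient fraction in steeply inclined regions
#'   (0 = off; a crude stand-in for concave-fold interreflection, present
#'   only so tests can confirm the cosine correction does not remove it).
#' @param noise list: `sigma` multiplicative Gaussian sd on reflectance
#'   (default 0), `sigma_z` height noise sd in mm (default 0).
#' @param holes list: `n` laser-shadow holes punched into the height map,
#'   `radius_px` their radius (defaults 0, 2).
#' @param working_distance mm (default 300).
#' @param falloff quadratic distance-falloff coefficients `c(c0, c1, c2)`
#'   of the white-standard intensity versus distance (mm), the ground truth
#'   of the height artifact and calibration.
#' @param seed integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(geometry = list(type = "hemisphere"),
                       material = phantom_params(3.7, 1.6),
                       model = NULL,
                       lambda_nm = default_grid(),
                       artifacts = list(),
                       noise = list(),
                       holes = list(),
                       working_distance = 300,
                       falloff = c(4.06, -1.64e-2, 2e-5),
                       seed = 1) {
  geometry <- utils::modifyList(
    list(type = "hemisphere", radius_mm = 15, tilt_deg = 20, npix = 41,
         pitch_mm = 0.8), geometry)
  artifacts <- utils::modifyList(
    list(lambert = TRUE, height = TRUE, interreflection = 0), artifacts)
  noise <- utils::modifyList(list(sigma = 0, sigma_z = 0), noise)
  holes <- utils::modifyList(list(n = 0, radius_px = 2), holes)
  if (is.null(model)) {
    model <- if (inherits(material, "skin_params")) "skin" else "phantom"
  }
  stopifnot(geometry$radius_mm > 0, noise$sigma >= 0, noise$sigma_z >= 0)
  structure(list(geometry = geometry, material = material, model = model,
                 lambda_nm = lambda_nm, artifacts = artifacts, noise = noise,
                 holes = holes, working_distance = working_distance,
                 falloff = falloff, seed = seed),
            class = "scene_spec")
}

scene_geometry <- function(spec) {
  g <- spec$geometry
  n <- g$npix
  pitch <- g$pitch_mm
  cx <- (n + 1) / 2
  x <- (col(matrix(0, n, n)) - cx) * pitch   # mm, sensor-line direction
  y <- (row(matrix(0, n, n)) - cx) * pitch   # mm, scan direction
  if (g$type == "hemisphere") {
    r2 <- x^2 + y^2
    R <- g$radius_mm
    z <- ifelse(r2 < R^2, sqrt(pmax(R^2 - r2, 0)), 0)
    on <- r2 < R^2
    nrm <- array(0, c(n, n, 3))
    nrm[, , 1] <- ifelse(on, x / R, 0)
    nrm[, , 2] <- ifelse(on, y / R, 0)
    nrm[, , 3] <- ifelse(on, z / R, 1)
    valid <- on
  } else if (g$type == "plane") {
    s <- tan(g$tilt_deg * pi / 180)
    z <- s * x - min(s * x)
    nn <- sqrt(1 + s^2)
    nrm <- array(0, c(n, n, 3))
    nrm[, , 1] <- -s / nn; nrm[, , 3] <- 1 / nn
    valid <- matrix(TRUE, n, n)
  } else if (g$type == "cylinder") {
    R <- g$radius_mm
    on <- abs(x) < R
    z <- ifelse(on, sqrt(pmax(R^2 - x^2, 0)), 0)
    nrm <- array(0, c(n, n, 3))
    nrm[, , 1] <- ifelse(on, x / R, 0)
    nrm[, , 3] <- ifelse(on, z / R, 1)
    valid <- on
  } else stop("unknown geometry type: ", g$type, call. = FALSE)
  list(z = z, normals = nrm, valid = valid)
}

#' Generate a synthetic scene
#'
#' Composes the forward pipeline the corrections assume: the material's
#' diffuse-reflectance spectrum (adding-doubling forward model) is painted
#' over the geometry, multiplied by `cos(theta)` (Lambert artifact) and by
#' the distance falloff `P(d)/P(working_distance)` (height artifact), an
#' optional additive interreflection term and multiplicative Gaussian noise
#' are applied, and a height map with Gaussian height noise and optional
#' laser-shadow holes is produced alongside the analytic surface normals and
#' the ground-truth parameters.
#'
#' @param spec a [scene_spec()].
#' @param fm optional prebuilt [forward_model()] matching `spec$model`
#'   (saves setup time in repeated calls).
#' @return A list with elements `cube` (artifact-laden
#'   [reflectance_cube()]), `cube_true` (artifact-free), `height`
#'   ([height_map()], noisy/holed), `height_true`, `normals` (analytic
#'   [normal_field()]), `truth` (named parameter vector), `spec`.
#' @export
generate_scene <- function(spec, fm = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  geo <- scene_geometry(spec)
  n <- spec$geometry$npix
  nl <- length(spec$lambda_nm)
  if (is.null(fm)) fm <- forward_model(spec$model, spec$lambda_nm)
  truth <- scene_truth(spec)
  rspec <- fm$forward(unname(truth[fm$par_names]))
  nf <- normal_field(geo$normals)
  ct <- cos_incidence(nf)
  P <- function(d) spec$falloff[1] + spec$falloff[2] * d + spec$falloff[3] * d^2
  dist <- spec$working_distance - geo$z
  eps_inv <- P(dist) / P(spec$working_distance)   # artifact factor (<= 1 above)
  fac <- matrix(1, n, n)
  if (isTRUE(spec$artifacts$lambert)) fac <- fac * pmax(ct, 0)
  if (isTRUE(spec$artifacts$height)) fac <- fac * eps_inv
  cube_t <- array(rep(rspec, each = n * n), c(n, n, nl))
  cube_a <- cube_t * array(rep(fac, nl), c(n, n, nl))
  if (spec$artifacts$interreflection > 0) {
    conc <- nf$theta > 45   # stand-in mask for concave/fold regions
    add <- spec$artifacts$interreflection *
      array(rep(rspec, each = n * n), c(n, n, nl)) *
      array(rep(conc, nl), c(n, n, nl))
    cube_a <- cube_a + add
  }
  out <- withr::with_seed(spec$seed, {
    if (spec$noise$sigma > 0) {
      cube_a <- cube_a * (1 + array(rnorm(length(cube_a), 0, spec$noise$sigma),
                                    dim(cube_a)))
    }
    z_meas <- geo$z
    if (spec$noise$sigma_z > 0) {
      z_meas <- z_meas + matrix(rnorm(n * n, 0, spec$noise$sigma_z), n, n)
    }
    hvalid <- matrix(TRUE, n, n)
    if (spec$holes$n > 0) {
      for (h in seq_len(spec$holes$n)) {
        hi <- sample.int(n, 1); hj <- sample.int(n, 1)
        d2 <- (row(z_meas) - hi)^2 + (col(z_meas) - hj)^2
        hvalid[d2 <= spec$holes$radius_px^2] <- FALSE
      }
    }
    list(cube_a = cube_a, z_meas = z_meas, hvalid = hvalid)
  })
  z_meas <- out$z_meas; z_meas[!out$hvalid] <- NA_real_
  pitch <- spec$geometry$pitch_mm
  list(
    cube = reflectance_cube(out$cube_a, spec$lambda_nm, pitch,
                            spec$working_distance, valid = geo$valid),
    cube_true = reflectance_cube(cube_t, spec$lambda_nm, pitch,
                                 spec$working_distance, valid = geo$valid),
    height = height_map(z_meas),
    height_true = height_map(geo$z),
    normals = nf,
    truth = truth,
    spec = spec
  )
}

scene_truth <- function(spec) {
  m <- spec$material
  if (spec$model == "phantom") {
    c(cabs_pct = m$cabs_pct, csc_pct = m$csc_pct)
  } else {
    c(fmel = m$fmel, fhb = m$fhb, fhbo2 = m$fhbo2, fcyt_red = m$fcyt_red,
      fcyt_ox = m$fcyt_ox, a = m$a)
  }
}

#' Skin parameters for the vascular occlusion test phases
#'
#' Configurable defaults reproducing the expected hemodynamics of a cuff
#' occlusion: deoxyhemoglobin rises during the occlusion (oxygen consumption
#' with blocked inflow) and drops after release; oxyhemoglobin falls during
#' and overshoots after release (reactive hyperaemia); melanin does not
#' change across phases.
#'
#' @param phase `"before"`, `"during"` or `"after"`.
#' @param fmel,a,fcyt_red,fcyt_ox phase-independent defaults.
#' @return A [skin_params()].
#' @export
vot_phase_params <- function(phase = c("before", "during", "after"),
                             fmel = 1.5, a = 30, fcyt_red = 0.3,
                             fcyt_ox = 0.3) {
  phase <- match.arg(phase)
  hb <- switch(phase, before = c(fhb = 1.0, fhbo2 = 3.0),
               during = c(fhb = 3.0, fhbo2 = 1.5),
               after = c(fhb = 0.5, fhbo2 = 5.0))
  skin_params(fmel = fmel, fhb = hb[["fhb"]], fhbo2 = hb[["fhbo2"]],
              fcyt_red = fcyt_red, fcyt_ox = fcyt_ox, a = a)
}

#' White-standard intensity stack for the distance calibration
#'
#' Simulates imaging the white standard at several distances under the
#' scene's quadratic falloff: the per-band mean intensities that
#' [fit_height_calibration()] consumes.
#'
#' @param spec a [scene_spec()].
#' @param distances mm (default: working distance +/- 20 mm in 5-mm steps).
#' @param n_bands number of bands (default: length of the scene grid).
#' @return A list with `intensities` (distances x bands) and `distances`.
#' @export
simulate_white_stack <- function(spec, distances = NULL, n_bands = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(distances)) {
    distances <- spec$working_distance + seq(-20, 20, by = 5)
  }
  if (is.null(n_bands)) n_bands <- length(spec$lambda_nm)
  P <- spec$falloff[1] + spec$falloff[2] * distances +
    spec$falloff[3] * distances^2
  list(intensities = matrix(rep(P, n_bands), ncol = n_bands),
       distances = distances)
}
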