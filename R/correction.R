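#' Quadratic height (distance) calibration
#'
#' The irradiance a pixel receives depends on the camera-to-surface distance.
#' The calibration is a per-band quadratic fit of mean white-standard
#' intensity against distance; the correction factor for a pixel at distance
#' `d` is `eps = P(working_distance) / P(d)`, equal to 1 at the working
#' distance by construction.
#'
#' @param coeffs numeric matrix `(bands, 3)` of quadratic coefficients
#'   `(c0, c1, c2)` so `P(d) = c0 + c1 d + c2 d^2`; a single row is recycled
#'   over bands (band-averaged scalar mode).
#' @param working_distance mm.
#' @param distance_range calibrated distance range, mm (length 2).
#' @return An object of class `height_calibration`.
#' @export
height_calibration <- function(coeffs, working_distance,
                               distance_range = working_distance + c(-20, 20)) {
  coeffs <- matrix(as.numeric(coeffs), ncol = 3)
  structure(list(coeffs = coeffs, working_distance = working_distance,
                 distance_range = sort(as.numeric(distance_range))),
            class = "height_calibration")
}

#' @export
print.height_calibration <- function(x, ...) {
  cat(sprintf("<height_calibration> %d band(s), working distance %.4g mm, range [%.4g, %.4g] mm\n",
              nrow(x$coeffs), x$working_distance,
              x$distance_range[1], x$distance_range[2]))
  invisible(x)
}

#' Fit the quadratic distance calibration from white-standard stacks
#'
#' Mean white-standard intensities recorded at several known distances are
#' least-squares fitted with a quadratic polynomial per band. Over the +/-20 mm
#' excursions typical of the imaging geometry a quadratic captures the
#' inverse-square irradiance falloff to well below a percent.
#'
#' @param intensities numeric matrix `(distances, bands)` (a vector is treated
#'   as one band) of mean white intensities.
#' @param distances numeric vector of distances, mm (>= 3 distinct values).
#' @param working_distance mm.
#' @return A [height_calibration()].
#' @export
fit_height_calibration <- function(intensities, distances, working_distance) {
  intensities <- as.matrix(intensities)
  d <- as.numeric(distances)
  if (length(unique(d)) < 3L) {
    stop("at least 3 distinct distances are required for a quadratic fit",
         call. = FALSE)
  }
  stopifnot(nrow(intensities) == length(d))
  X <- cbind(1, d, d^2)
  coeffs <- t(qr.solve(X, intensities))   # (bands, 3)
  fitted_range <- X %*% t(coeffs)
  if (any(fitted_range <= 0)) {
    warning("fitted calibration polynomial non-positive at some calibrated distances",
            call. = FALSE)
  }
  height_calibration(coeffs, working_distance, range(d))
}

eval_calibration <- function(cal, d, band) {
  b <- if (nrow(cal$coeffs) == 1L) 1L else band
  cal$coeffs[b, 1L] + cal$coeffs[b, 2L] * d + cal$coeffs[b, 3L] * d^2
}

#' Height (distance) correction of a reflectance cube
#'
#' Multiplies each pixel and band by `eps(lambda) = P(working_distance) /
#' P(d)` where `d = working_distance - z` is the actual camera-to-surface
#' distance and `P` the per-band calibration polynomial. Pixels whose distance
#' falls outside the calibrated range are corrected by extrapolation but
#' flagged invalid, with a warning.
#'
#' @param cube a [reflectance_cube()].
#' @param h a fully valid [height_map()] co-registered with the cube.
#' @param cal a [height_calibration()] with either one row (band-averaged
#'   mode) or one row per band of the cube.
#' @return A corrected [reflectance_cube()] with `"height"` appended to its
#'   correction provenance.
#' @export
height_correct <- function(cube, h, cal) {
  stopifnot(inherits(cube, "reflectance_cube"), inherits(h, "height_map"),
            inherits(cal, "height_calibration"))
  d <- dim(cube$values)
  stopifnot(identical(dim(h$z), d[1:2]))
  if (nrow(cal$coeffs) != 1L && nrow(cal$coeffs) != d[3L]) {
    stop("calibration must have 1 band or match the cube's band count",
         call. = FALSE)
  }
  dist <- cube$working_distance - h$z
  out_of_range <- h$valid &
    (dist < cal$distance_range[1] | dist > cal$distance_range[2])
  if (any(out_of_range)) {
    warning(sprintf("%d pixel(s) outside the calibrated distance range; flagged invalid",
                    sum(out_of_range)), call. = FALSE)
  }
  vals <- cube$values
  valid <- cube$valid & h$valid & !out_of_range
  for (l in seq_len(d[3L])) {
    p_wd <- eval_calibration(cal, cal$working_distance, l)
    eps <- p_wd / eval_calibration(cal, dist, l)
    band <- vals[, , l] * eps
    band[!valid] <- vals[, , l][!valid]   # never alter masked pixels
    vals[, , l] <- band
  }
  reflectance_cube(vals, cube$wavelengths, cube$pixel_pitch,
                   cube$working_distance, valid,
                   corrections = union(cube$corrections, "height"))
}

#' Lambert cosine correction of a (height-corrected) reflectance cube
#'
#' Divides each pixel and band of the height-corrected reflectance by the
#' cosine of the local illumination incidence angle. Pixels with
#' `cos(theta) < min_cos` are masked invalid: beyond roughly 84 deg the
#' `1/cos` factor amplifies noise without bound and profilometry is
#' unreliable there.
#'
#' @param cube a [reflectance_cube()]; must carry the `"height"` correction
#'   flag unless `require_height = FALSE`.
#' @param cos_theta numeric matrix of incidence cosines (from
#'   [cos_incidence()]), co-registered with the cube.
#' @param min_cos validity threshold on `cos(theta)` (default 0.1).
#' @param require_height enforce the height-then-Lambert order (default TRUE).
#' @return A corrected [reflectance_cube()] with `"lambert"` appended to its
#'   correction provenance.
#' @export
lambert_correct <- function(cube, cos_theta, min_cos = 0.1,
                            require_height = TRUE) {
  stopifnot(inherits(cube, "reflectance_cube"))
  if (missing(cos_theta) || is.null(cos_theta)) {
    stop("cos_theta field is required", call. = FALSE)
  }
  if (require_height && !("height" %in% cube$corrections)) {
    stop("cube is not height-corrected; run height_correct() first or set require_height = FALSE",
         call. = FALSE)
  }
  d <- dim(cube$values)
  stopifnot(identical(dim(cos_theta), d[1:2]))
  valid <- cube$valid & is.finite(cos_theta) & cos_theta >= min_cos
  vals <- cube$values
  ct <- cos_theta
  ct[!valid] <- 1   # leave masked pixels untouched
  for (l in seq_len(d[3L])) vals[, , l] <- vals[, , l] / ct
  reflectance_cube(vals, cube$wavelengths, cube$pixel_pitch,
                   cube$working_distance, valid,
                   corrections = union(cube$corrections, "lambert"))
}
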