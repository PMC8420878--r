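#' Raw hyperspectral scan (sample, dark and white frames)
#'
#' Container for the three frame sets a pushbroom acquisition produces: the raw
#' sample counts, the dark-current counts at the same integration time, and the
#' counts from a diffuse white reflectance standard. Reflectance is obtained
#' with [normalize_reflectance()] as `(raw - dark) / (white - dark)`,
#' elementwise per pixel and band.
#'
#' @param raw numeric array `(rows, cols, bands)` of sample counts.
#' @param dark numeric matrix `(rows, cols)` of dark counts, or an array
#'   `(rows, cols, bands)` if the dark frame is band-resolved.
#' @param white numeric array `(rows, cols, bands)` of white-standard counts.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, length `bands`.
#'
#' @return An object of class `raw_scan`.
#' @seealso [normalize_reflectance()], [reflectance_cube()]
#' @export
raw_scan <- function(raw, dark, white, wavelengths) {
  raw <- as_cube_array(raw)
  white <- as_cube_array(white)
  if (length(dim(dark)) == 2L) {
    if (!identical(dim(dark), dim(raw)[1:2])) {
      stop("raw, dark and white frames must share the same (rows, cols, bands) grid",
           call. = FALSE)
    }
    dark <- array(rep(as.matrix(dark), dim(raw)[3L]), dim = dim(raw))
  } else {
    dark <- as_cube_array(dark)
  }
  if (!identical(dim(raw), dim(white)) || !identical(dim(raw), dim(dark))) {
    stop("raw, dark and white frames must share the same (rows, cols, bands) grid",
         call. = FALSE)
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(raw)[3L]) {
    stop("length(wavelengths) must equal the number of bands", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  structure(
    list(raw = raw, dark = dark, white = white, wavelengths = wavelengths),
    class = "raw_scan"
  )
}

as_cube_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L) {
    stop("expected an array with dimensions (rows, cols, bands)", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Normalized reflectance datacube
#'
#' Wavelength-resolved, dimensionless reflectance on a regular pixel grid.
#' The first array index is the scan direction (rows, Y), the second the sensor
#' line (columns, X), the third the spectral band. Values may be negative where
#' noise dips below the dark level; such pixels are excluded via the validity
#' mask rather than clipped, because clipping biases downstream fits.
#'
#' @param values numeric array `(rows, cols, bands)` of reflectance.
#' @param wavelengths numeric vector, nm, strictly increasing.
#' @param pixel_pitch length-2 numeric, mm/pixel in (X, Y); a scalar is
#'   recycled.
#' @param working_distance camera working distance in mm (default 300).
#' @param valid logical matrix `(rows, cols)`; `NULL` means all valid.
#' @param corrections character vector recording applied corrections
#'   (provenance), e.g. `"height"`, `"lambert"`.
#'
#' @return An object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(values, wavelengths, pixel_pitch = c(1, 1),
                             working_distance = 300, valid = NULL,
                             corrections = character()) {
  values <- as_cube_array(values)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3L]) {
    stop("length(wavelengths) must equal the number of bands", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (length(pixel_pitch) == 1L) pixel_pitch <- rep(pixel_pitch, 2L)
  if (is.null(valid)) {
    valid <- matrix(TRUE, dim(values)[1L], dim(values)[2L])
  }
  stopifnot(identical(dim(valid), dim(values)[1:2]))
  structure(
    list(values = values, wavelengths = wavelengths,
         pixel_pitch = as.numeric(pixel_pitch),
         working_distance = as.numeric(working_distance),
         valid = valid, corrections = corrections),
    class = "reflectance_cube"
  )
}

#' @export
print.raw_scan <- function(x, ...) {
  d <- dim(x$raw)
  cat(sprintf("<raw_scan> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<reflectance_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  pixel pitch %.3g x %.3g mm, working distance %.4g mm\n",
              x$pixel_pitch[1], x$pixel_pitch[2], x$working_distance))
  cat(sprintf("  valid pixels: %d / %d; corrections: %s\n",
              sum(x$valid), length(x$valid),
              if (length(x$corrections)) paste(x$corrections, collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
dim.reflectance_cube <- function(x) dim(x$values)

#' Normalize a raw scan to reflectance
#'
#' Converts raw counts to dimensionless reflectance per pixel and band:
#' `I = (R - D) / (W - D)` where `R` is the sample frame, `D` the dark frame
#' and `W` the white-standard frame. Voxels where `W - D <= 0` carry no
#' calibration information; the affected pixels are flagged invalid (their
#' values set to `NA`) rather than silently clipped.
#'
#' @param scan a [raw_scan()].
#' @param pixel_pitch,working_distance grid metadata propagated to the result.
#'
#' @return A [reflectance_cube()].
#' @examples
#' sc <- raw_scan(array(600, c(2, 2, 1)), matrix(100, 2, 2),
#'                array(1100, c(2, 2, 1)), 550)
#' normalize_reflectance(sc)$values[1, 1, 1]  # 0.5
#' @export
normalize_reflectance <- function(scan, pixel_pitch = c(1, 1),
                                  working_distance = 300) {
  stopifnot(inherits(scan, "raw_scan"))
  denom <- scan$white - scan$dark
  bad <- denom <= 0
  vals <- (scan$raw - scan$dark) / denom
  valid <- !apply(bad, c(1, 2), any)
  if (any(bad)) {
    vals[bad] <- NA_real_
    warning(sprintf(
      "%d voxel(s) with non-positive white-dark denominator; pixels flagged invalid",
      sum(bad)), call. = FALSE)
  }
  reflectance_cube(vals, scan$wavelengths, pixel_pitch = pixel_pitch,
                   working_distance = working_distance, valid = valid)
}

#' Bin a reflectance cube spatially and spectrally
#'
#' Block means over non-overlapping windows of `spatial_factor` pixels in each
#' spatial direction and `spectral_factor` bands. Trailing partial blocks are
#' dropped. The pixel pitch is multiplied by the spatial factor and the
#' wavelength axis is replaced by block-mean wavelengths. A binned pixel is
#' valid only if all pixels of its block were valid.
#'
#' @param cube a [reflectance_cube()].
#' @param spatial_factor,spectral_factor integer block sizes (>= 1).
#'
#' @return A [reflectance_cube()] of reduced shape.
#' @export
bin_cube <- function(cube, spatial_factor = 8L, spectral_factor = 6L) {
  stopifnot(inherits(cube, "reflectance_cube"))
  fs <- as.integer(spatial_factor)
  fl <- as.integer(spectral_factor)
  if (fs < 1L || fl < 1L) stop("binning factors must be >= 1", call. = FALSE)
  d <- dim(cube$values)
  if (fs > d[1L] || fs > d[2L] || fl > d[3L]) {
    stop("binning factor larger than the corresponding axis length", call. = FALSE)
  }
  ni <- d[1L] %/% fs; nj <- d[2L] %/% fs; nl <- d[3L] %/% fl
  v <- cube$values[seq_len(ni * fs), seq_len(nj * fs), seq_len(nl * fl),
                   drop = FALSE]
  # block mean via dimension folding; preserves (i, j) orientation
  v <- array(v, dim = c(fs, ni, fs, nj, fl, nl))
  out <- apply(v, c(2, 4, 6), mean)
  vd <- cube$valid[seq_len(ni * fs), seq_len(nj * fs), drop = FALSE]
  vd <- array(vd, dim = c(fs, ni, fs, nj))
  valid <- apply(vd, c(2, 4), all)
  wl <- colMeans(matrix(cube$wavelengths[seq_len(nl * fl)], nrow = fl))
  reflectance_cube(out, wl,
                   pixel_pitch = cube$pixel_pitch * fs,
                   working_distance = cube$working_distance,
                   valid = valid, corrections = cube$corrections)
}

#' Extract the spectrum of a single pixel as a tibble
#'
#' @param cube a [reflectance_cube()].
#' @param i,j 1-based pixel row/column.
#' @return A tibble with columns `wavelength_nm`, `reflectance`.
#' @export
cube_spectrum <- function(cube, i, j) {
  stopifnot(inherits(cube, "reflectance_cube"))
  tibble::tibble(wavelength_nm = cube$wavelengths,
                 reflectance = as.numeric(cube$values[i, j, ]))
}

#' Mean spectrum over a rectangular region
#'
#' @param cube a [reflectance_cube()].
#' @param rows,cols integer index vectors (default: whole grid). Invalid
#'   pixels are excluded.
#' @return A tibble with columns `wavelength_nm`, `reflectance`.
#' @export
region_spectrum <- function(cube, rows = NULL, cols = NULL) {
  stopifnot(inherits(cube, "reflectance_cube"))
  d <- dim(cube$values)
  if (is.null(rows)) rows <- seq_len(d[1L])
  if (is.null(cols)) cols <- seq_len(d[2L])
  sub <- cube$values[rows, cols, , drop = FALSE]
  ok <- cube$valid[rows, cols, drop = FALSE]
  spec <- vapply(seq_len(d[3L]), function(l) {
    band <- sub[, , l]
    mean(band[ok], na.rm = TRUE)
  }, numeric(1))
  tibble::tibble(wavelength_nm = cube$wavelengths, reflectance = spec)
}
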