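#' Radial average of a parameter map
#'
#' Mean and standard deviation of a fitted parameter over concentric annuli
#' around a centre (default: the grid centre), in physical units via the
#' map's pixel pitch. If an inclination-angle field is supplied, its annulus
#' mean is reported alongside, which lets profiles be read as functions of
#' inclination.
#'
#' @param map a `parameter_map` from [fit_cube()] (or a plain matrix).
#' @param param parameter name (default: first fitted parameter).
#' @param center `c(i, j)` pixel coordinates of the centre (default: grid
#'   centre).
#' @param bin_width_mm annulus width, mm (default: one binned pixel).
#' @param theta optional matrix of inclination angles (deg) on the map grid.
#' @return A tibble with columns `radius_mm` (annulus mid-radius), `mean`,
#'   `sd`, `n`, and `theta_deg` (annulus-mean inclination; `NA` if no theta
#'   given). Empty annuli are reported with `n = 0` and `NA` statistics.
#' @export
radial_average <- function(map, param = NULL, center = NULL,
                           bin_width_mm = NULL, theta = NULL) {
  if (inherits(map, "parameter_map")) {
    m <- map_matrix(map, param)
    pitch <- map$pixel_pitch
  } else {
    m <- as.matrix(map)
    pitch <- c(1, 1)
  }
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc) {
    stop("center must lie inside the map", call. = FALSE)
  }
  if (is.null(bin_width_mm)) bin_width_mm <- mean(pitch)
  xi <- (row(m) - center[1]) * pitch[2]
  xj <- (col(m) - center[2]) * pitch[1]
  r <- sqrt(xi^2 + xj^2)
  rmax <- max(r)
  breaks <- seq(0, rmax + bin_width_mm, by = bin_width_mm)
  bin <- findInterval(r, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  out <- lapply(seq_len(nb), function(b) {
    sel <- bin == b & is.finite(m)
    v <- m[sel]
    tibble::tibble(
      radius_mm = (breaks[b] + breaks[b + 1]) / 2,
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else if (length(v)) 0 else NA_real_,
      n = length(v),
      theta_deg = if (!is.null(theta) && length(v)) mean(theta[sel],
                                                        na.rm = TRUE)
                  else NA_real_)
  })
  dplyr::bind_rows(out)
}

#' Maximum inclination angle with parameters within tolerance of the centre
#'
#' Scans the radial profile in order of increasing inclination angle and
#' returns the largest angle such that every annulus at or below it deviates
#' from the central value by at most `tol` (relative). The central value
#' defaults to the mean over the flat central region (annuli with
#' inclination below `central_theta` degrees).
#'
#' @param profile a tibble from [radial_average()] with a `theta_deg` column.
#' @param central_value reference value; default: mean of the central-region
#'   annuli.
#' @param tol relative tolerance (default 0.05).
#' @param central_theta inclination defining the flat central region, deg
#'   (default 10).
#' @return The maximum valid inclination angle in degrees (0 if even the
#'   innermost annulus deviates).
#' @export
max_valid_angle <- function(profile, central_value = NULL, tol = 0.05,
                            central_theta = 10) {
  stopifnot(all(c("theta_deg", "mean") %in% names(profile)))
  p <- profile[is.finite(profile$theta_deg) & is.finite(profile$mean), ]
  if (!nrow(p)) return(0)
  p <- p[order(p$theta_deg), ]
  if (is.null(central_value)) {
    central <- p$mean[p$theta_deg <= central_theta]
    if (!length(central)) central <- p$mean[1]
    central_value <- mean(central)
  }
  ok <- abs(p$mean - central_value) / abs(central_value) <= tol
  if (!ok[1]) return(0)
  first_bad <- which(!ok)[1]
  if (is.na(first_bad)) return(max(p$theta_deg))
  p$theta_deg[first_bad - 1L]
}
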