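#' Height map on the cube pixel grid
#'
#' Surface height in mm per pixel, with a validity mask marking points the
#' profilometer could not reach (laser shadowing). Heights increase toward the
#' camera: the camera-to-surface distance is `working_distance - z`.
#'
#' @param z numeric matrix `(rows, cols)`, mm; may contain `NA` at invalid
#'   points.
#' @param valid logical matrix; defaults to `!is.na(z)`.
#' @return An object of class `height_map`.
#' @export
height_map <- function(z, valid = NULL) {
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (is.null(valid)) valid <- !is.na(z)
  valid <- as.matrix(valid)
  stopifnot(identical(dim(valid), dim(z)))
  if (any(valid & !is.finite(z))) {
    stop("z must be finite wherever valid", call. = FALSE)
  }
  structure(list(z = z, valid = valid), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d, valid %d / %d, z in [%.3g, %.3g] mm\n",
              nrow(x$z), ncol(x$z), sum(x$valid), length(x$valid),
              min(x$z[x$valid]), max(x$z[x$valid])))
  invisible(x)
}

#' Laser-line triangulation geometry
#'
#' Geometry of a laser-line profilometer: the laser sheet hits the surface at
#' incidence angle `alpha`, a camera observes it at angle `beta` from a
#' baseline `L` away, through a lens of focal length `f`. A lateral line
#' displacement `dy` on the detector maps to a height difference via
#' [triangulate_height()].
#'
#' @param L laser-camera baseline, mm (> 0).
#' @param alpha laser incidence angle, degrees in (0, 90).
#' @param beta camera observation angle, degrees in (0, 90).
#' @param f lens focal length, mm (> 0).
#' @return An object of class `profilometer_geometry`.
#' @export
profilometer_geometry <- function(L, alpha, beta, f) {
  stopifnot(L > 0, f > 0, alpha > 0, alpha < 90, beta > 0, beta < 90)
  structure(list(L = L, alpha = alpha, beta = beta, f = f),
            class = "profilometer_geometry")
}

#' Height from laser-line displacement
#'
#' Converts the recorded laser-line displacement into a surface height
#' difference: `dz = L / (tan(beta) + tan(alpha - atan(dy / f)))`. Each entry
#' is interpreted per measured point (the relative displacement against the
#' reference line position); anchoring of absolute height is up to the caller.
#' Points where the denominator is non-positive (geometrically impossible ray
#' configuration) or where `dy` is missing are marked invalid.
#'
#' @param dy numeric matrix (or vector) of line displacements in mm on the
#'   detector; `NA` marks unmeasured points.
#' @param geom a [profilometer_geometry()].
#' @return A [height_map()] of `dz` values, mm.
#' @export
triangulate_height <- function(dy, geom) {
  stopifnot(inherits(geom, "profilometer_geometry"))
  dy <- as.matrix(dy)
  a <- geom$alpha * pi / 180
  b <- geom$beta * pi / 180
  denom <- tan(b) + tan(a - atan(dy / geom$f))
  dz <- geom$L / denom
  bad <- is.finite(denom) & denom <= 0
  if (any(bad)) {
    warning(sprintf("%d point(s) with non-positive triangulation denominator invalidated",
                    sum(bad)), call. = FALSE)
    dz[bad] <- NA_real_
  }
  dz[!is.finite(dz)] <- NA_real_
  height_map(dz)
}

#' Fill height-map holes by Laplace (harmonic) interpolation
#'
#' Missing points are replaced by the solution of the discrete Laplace
#' equation on the holes (5-point stencil, zero Laplacian) with Dirichlet data
#' taken from the valid neighbours; at the grid border the stencil uses the
#' available neighbours only. Valid points are untouched. The filled values
#' obey the discrete maximum principle: they lie within the range of the
#' boundary data. The sparse symmetric positive-definite system is solved
#' directly by a sparse Cholesky factorization, which is exact to solver
#' precision (far below the 1e-8 relative-residual requirement).
#'
#' @param h a [height_map()] with at least one valid point.
#' @return A fully valid [height_map()].
#' @export
laplace_fill <- function(h) {
  stopifnot(inherits(h, "height_map"))
  if (!any(h$valid)) stop("height map has no valid points to interpolate from",
                          call. = FALSE)
  if (all(h$valid)) return(h)
  z <- h$z
  nr <- nrow(z); nc <- ncol(z)
  miss <- which(!h$valid)
  idx <- matrix(0L, nr, nc)
  idx[miss] <- seq_along(miss)
  mi <- ((miss - 1L) %% nr) + 1L
  mj <- ((miss - 1L) %/% nr) + 1L
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rhs <- numeric(length(miss))
  deg <- numeric(length(miss))
  for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ni <- mi + s[1L]; nj <- mj + s[2L]
    inside <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
    lin <- (nj[inside] - 1L) * nr + ni[inside]
    deg[inside] <- deg[inside] + 1
    nb_missing <- idx[lin] > 0L
    # neighbour is another unknown -> off-diagonal entry
    from <- which(inside)[nb_missing]
    trip_i <- c(trip_i, from)
    trip_j <- c(trip_j, idx[lin][nb_missing])
    trip_x <- c(trip_x, rep(-1, sum(nb_missing)))
    # neighbour is known -> Dirichlet contribution
    from_k <- which(inside)[!nb_missing]
    rhs[from_k] <- rhs[from_k] + z[lin[!nb_missing]]
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_along(miss), trip_i),
    j = c(seq_along(miss), trip_j),
    x = c(deg, trip_x),
    dims = c(length(miss), length(miss))
  )
  sol <- Matrix::solve(A, rhs)
  z[miss] <- as.numeric(sol)
  height_map(z, matrix(TRUE, nr, nc))
}

#' Surface unit normals and inclination angles
#'
#' Gradients of the height field are estimated by central differences
#' (one-sided at the borders), optionally after a Gaussian pre-smooth. The
#' unit normal is `(-dz/dx, -dz/dy, 1)` normalized, oriented toward the
#' camera. The inclination angle `theta` is measured against the illumination
#' direction `l` (default: the vertical optical axis).
#'
#' @param h a fully valid [height_map()] (apply [laplace_fill()] first).
#' @param pixel_pitch mm per pixel in (X = columns, Y = rows); scalar recycled.
#' @param l unit illumination direction, default `c(0, 0, 1)`.
#' @param smooth_sigma optional Gaussian smoothing sigma in pixels (0 = none).
#' @return An object of class `normal_field` with unit-normal array
#'   `n (rows, cols, 3)` and inclination angles `theta` in degrees.
#' @export
compute_normals <- function(h, pixel_pitch = c(1, 1), l = c(0, 0, 1),
                            smooth_sigma = 0) {
  stopifnot(inherits(h, "height_map"))
  if (!all(h$valid)) stop("height map must be fully valid; run laplace_fill() first",
                          call. = FALSE)
  if (length(pixel_pitch) == 1L) pixel_pitch <- rep(pixel_pitch, 2L)
  z <- h$z
  if (smooth_sigma > 0) z <- gauss_smooth(z, smooth_sigma)
  # x = column direction, y = row direction
  zx <- central_diff(z, along = 2L) / pixel_pitch[1L]
  zy <- central_diff(z, along = 1L) / pixel_pitch[2L]
  nrm <- sqrt(zx^2 + zy^2 + 1)
  n <- array(c(-zx / nrm, -zy / nrm, 1 / nrm), dim = c(dim(z), 3L))
  normal_field(n, l)
}

#' Construct a normal field from a unit-normal array
#'
#' @param n array `(rows, cols, 3)` of unit normals.
#' @param l unit illumination direction.
#' @return A `normal_field` with `n`, `theta` (deg) and `l`.
#' @export
normal_field <- function(n, l = c(0, 0, 1)) {
  stopifnot(length(dim(n)) == 3L, dim(n)[3L] == 3L)
  l <- l / sqrt(sum(l^2))
  ct <- pmin(pmax(n[, , 1] * l[1] + n[, , 2] * l[2] + n[, , 3] * l[3], -1), 1)
  structure(list(n = n, theta = acos(ct) * 180 / pi, l = l),
            class = "normal_field")
}

#' @export
print.normal_field <- function(x, ...) {
  cat(sprintf("<normal_field> %d x %d, theta in [%.2f, %.2f] deg\n",
              nrow(x$theta), ncol(x$theta), min(x$theta), max(x$theta)))
  invisible(x)
}

#' Cosine of the incidence angle per pixel
#'
#' For unit surface normals `n` and a unit illumination direction `l` the
#' normalized projection reduces to the dot product `cos(theta) = n . l`,
#' clipped to `[-1, 1]`.
#'
#' @param nf a [normal_field()].
#' @param l unit illumination direction; default: the field's own `l`.
#' @return Numeric matrix of `cos(theta)`.
#' @export
cos_incidence <- function(nf, l = NULL) {
  stopifnot(inherits(nf, "normal_field"))
  if (is.null(l)) l <- nf$l
  l <- l / sqrt(sum(l^2))
  ct <- nf$n[, , 1] * l[1] + nf$n[, , 2] * l[2] + nf$n[, , 3] * l[3]
  pmin(pmax(ct, -1), 1)
}

central_diff <- function(z, along) {
  if (along == 2L) {
    nc <- ncol(z)
    if (nc < 2L) return(matrix(0, nrow(z), nc))
    g <- z
    g[, 2:(nc - 1)] <- (z[, 3:nc, drop = FALSE] - z[, 1:(nc - 2), drop = FALSE]) / 2
    g[, 1] <- z[, 2] - z[, 1]
    g[, nc] <- z[, nc] - z[, nc - 1]
    g
  } else {
    t(central_diff(t(z), along = 2L))
  }
}

gauss_smooth <- function(z, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # separable convolution with edge replication
  pad_apply <- function(m) {
    nc <- ncol(m)
    mp <- cbind(m[, rep(1L, r), drop = FALSE], m, m[, rep(nc, r), drop = FALSE])
    out <- matrix(0, nrow(m), nc)
    for (s in seq_along(k)) {
      out <- out + k[s] * mp[, s:(s + nc - 1), drop = FALSE]
    }
    out
  }
  t(pad_apply(t(pad_apply(z))))
}

#' Register a height map onto a cube's pixel grid by an affine transform
#'
#' Resamples the height field so that cube pixel `(i, j)` takes the value at
#' height-map coordinates `A %*% c(i, j) + t` (bilinear interpolation).
#' Coefficients come from an external calibration of the two instruments'
#' geometry; the identity default covers pre-registered data such as the
#' synthetic scenes. Target pixels that map outside the source grid, or whose
#' bilinear support contains invalid points, are marked invalid (fill with
#' [laplace_fill()] afterwards if needed).
#'
#' @param h a [height_map()] on the source grid.
#' @param shape target grid `c(rows, cols)` (e.g. `dim(cube)[1:2]`).
#' @param A 2 x 2 affine matrix (default identity).
#' @param t length-2 offset in pixels (default `c(0, 0)`).
#' @return A [height_map()] on the target grid.
#' @export
register_height <- function(h, shape, A = diag(2), t = c(0, 0)) {
  stopifnot(inherits(h, "height_map"), length(shape) == 2L)
  A <- matrix(A, 2, 2)
  nr <- nrow(h$z); nc <- ncol(h$z)
  zi <- matrix(NA_real_, shape[1], shape[2])
  vi <- matrix(FALSE, shape[1], shape[2])
  ii <- rep(seq_len(shape[1]), times = shape[2])
  jj <- rep(seq_len(shape[2]), each = shape[1])
  src <- cbind(A[1, 1] * ii + A[1, 2] * jj + t[1],
               A[2, 1] * ii + A[2, 2] * jj + t[2])
  i0 <- floor(src[, 1]); j0 <- floor(src[, 2])
  fi <- src[, 1] - i0; fj <- src[, 2] - j0
  inside <- i0 >= 1 & i0 + 1 <= nr & j0 >= 1 & j0 + 1 <= nc
  # degenerate-but-exact corner: integer coordinates on the last row/col
  exact <- i0 >= 1 & i0 <= nr & j0 >= 1 & j0 <= nc & fi == 0 & fj == 0
  for (s in which(inside | exact)) {
    if (fi[s] == 0 && fj[s] == 0) {
      if (h$valid[i0[s], j0[s]]) {
        zi[ii[s], jj[s]] <- h$z[i0[s], j0[s]]
        vi[ii[s], jj[s]] <- TRUE
      }
      next
    }
    if (!inside[s]) next
    ok <- h$valid[i0[s], j0[s]] && h$valid[i0[s] + 1, j0[s]] &&
      h$valid[i0[s], j0[s] + 1] && h$valid[i0[s] + 1, j0[s] + 1]
    if (!ok) next
    z00 <- h$z[i0[s], j0[s]]; z10 <- h$z[i0[s] + 1, j0[s]]
    z01 <- h$z[i0[s], j0[s] + 1]; z11 <- h$z[i0[s] + 1, j0[s] + 1]
    zi[ii[s], jj[s]] <- (1 - fi[s]) * (1 - fj[s]) * z00 +
      fi[s] * (1 - fj[s]) * z10 + (1 - fi[s]) * fj[s] * z01 +
      fi[s] * fj[s] * z11
    vi[ii[s], jj[s]] <- TRUE
  }
  height_map(zi, vi)
}
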