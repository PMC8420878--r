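#' Lorenz-Mie efficiencies of a homogeneous sphere
#'
#' Scattering/extinction efficiencies and the asymmetry parameter of a
#' homogeneous sphere embedded in a non-absorbing medium, by the standard
#' partial-wave series. The series is truncated after
#' `x + 4.05 x^(1/3) + 2` terms (Wiscombe criterion); the logarithmic
#' derivative is computed by downward recurrence, the Riccati-Bessel
#' functions by upward recurrence. The sphere index may be complex
#' (absorbing); the medium index must be real.
#'
#' @param radius_um sphere radius, micrometres (> 0).
#' @param lambda_nm vacuum wavelength, nm (vectorized).
#' @param n_sphere sphere refractive index (possibly complex).
#' @param n_medium medium refractive index (real).
#' @return A tibble with columns `lambda_nm`, `x` (size parameter), `qsca`,
#'   `qext`, `qabs`, `g`.
#' @examples
#' mie_sphere(7, 600, 1.46, 1.41)
#' @export
mie_sphere <- function(radius_um, lambda_nm, n_sphere, n_medium) {
  stopifnot(radius_um > 0, all(lambda_nm > 0), all(Re(n_medium) == n_medium))
  ns <- eval_index(n_sphere, lambda_nm)
  nm <- eval_index(n_medium, lambda_nm)
  res <- lapply(seq_along(lambda_nm), function(i) {
    x <- 2 * pi * radius_um * nm[i] / (lambda_nm[i] / 1000)
    mie_single(x, ns[i] / nm[i])
  })
  out <- do.call(rbind, res)
  tibble::tibble(lambda_nm = as.numeric(lambda_nm),
                 x = out[, 1], qsca = out[, 2], qext = out[, 3],
                 qabs = out[, 4], g = out[, 5])
}

mie_single <- function(x, m) {
  if (!is.finite(x) || x <= 0) stop("size parameter must be positive and finite",
                                    call. = FALSE)
  nmax <- ceiling(x + 4.05 * x^(1 / 3) + 2)
  if (nmax > 20000) stop("Mie series does not converge for this size parameter",
                         call. = FALSE)
  mx <- m * x
  nmx <- max(nmax, ceiling(Mod(mx))) + 16L
  # downward recurrence for the logarithmic derivative:
  # D_{n-1}(mx) = n/mx - 1 / (D_n(mx) + n/mx), seeded with D = 0 high up
  D <- complex(length.out = nmx)
  for (n in nmx:2L) {
    D[n - 1L] <- (n / mx) - 1 / (D[n] + n / mx)
  }
  a <- complex(length.out = nmax)
  b <- complex(length.out = nmax)
  psi_m1 <- cos(x); psi0 <- sin(x)          # psi_{n-1}, psi_n at n = 0
  chi_m1 <- -sin(x); chi0 <- cos(x)
  psi_prev <- psi0; psi_pprev <- psi_m1
  chi_prev <- chi0; chi_pprev <- chi_m1
  for (n in seq_len(nmax)) {
    psi <- (2 * n - 1) / x * psi_prev - psi_pprev
    chi <- (2 * n - 1) / x * chi_prev - chi_pprev
    xi <- complex(real = psi, imaginary = -chi)
    xi_prev <- complex(real = psi_prev, imaginary = -chi_prev)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    a[n] <- (da * psi - psi_prev) / (da * xi - xi_prev)
    b[n] <- (db * psi - psi_prev) / (db * xi - xi_prev)
    psi_pprev <- psi_prev; psi_prev <- psi
    chi_pprev <- chi_prev; chi_prev <- chi
  }
  n <- seq_len(nmax)
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  qext <- (2 / x^2) * sum((2 * n + 1) * Re(a + b))
  n1 <- n[-nmax]
  gsum <- sum(n1 * (n1 + 2) / (n1 + 1) *
                Re(a[n1] * Conj(a[n1 + 1]) + b[n1] * Conj(b[n1 + 1]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- if (qsca > 0) 4 / x^2 * gsum / qsca else 0
  c(x, qsca, qext, max(qext - qsca, 0), g)
}

#' Polydisperse sphere size distribution
#'
#' Volume fraction per radius bin of the scatterer's sphere population. The
#' volume fractions are relative to unit volume of raw scatterer: they sum to
#' the total sphere volume fraction of the raw powder (not necessarily 1).
#'
#' @param radii_um numeric vector of bin-centre radii, micrometres.
#' @param volume_fraction numeric vector of per-bin volume fractions (>= 0).
#' @return An object of class `sphere_distribution`.
#' @export
sphere_distribution <- function(radii_um, volume_fraction) {
  stopifnot(length(radii_um) == length(volume_fraction),
            all(radii_um > 0), all(volume_fraction >= 0))
  if (!length(radii_um)) stop("empty sphere distribution", call. = FALSE)
  structure(list(radii_um = as.numeric(radii_um),
                 volume_fraction = as.numeric(volume_fraction)),
            class = "sphere_distribution")
}

#' Read a sphere distribution from CSV
#'
#' Expects columns `radius_um` and `volume_fraction`. The bundled
#' `sphere_distribution_synthetic.csv` is a synthetic stand-in for a measured
#' microsphere population: a log-normal volume-fraction distribution with
#' support 1-16 um, weighted toward small radii and scaled so that, together
#' with the shell-dominated effective sphere index, the scattering library
#' spans the reduced-scattering range of the silicone phantom recipe
#' (about 8-40 1/cm over scatterer fractions of 1.6-7 %).
#'
#' @param path CSV path; default: the bundled synthetic distribution.
#' @return A [sphere_distribution()].
#' @export
read_sphere_distribution <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sphere_distribution_synthetic.csv",
                        package = "hsicurve", mustWork = TRUE)
  }
  df <- utils::read.csv(path)
  sphere_distribution(df$radius_um, df$volume_fraction)
}

#' Scattering coefficient and anisotropy of a polydisperse suspension
#'
#' Per radius bin the scattering coefficient contribution of volume fraction
#' `phi_i` of spheres of radius `r_i` is `mus_i = 3 phi_i Qsca_i / (4 r_i)`.
#' The library coefficient `mus_cal` (per unit raw-scatterer volume fraction)
#' is the sum over bins, and the suspension anisotropy is the
#' scattering-weighted mean of the single-sphere asymmetry parameters. The
#' final coefficient at scatterer volume fraction `Csc` is `Csc * mus_cal`.
#'
#' @param dist a [sphere_distribution()].
#' @param lambda_nm wavelength grid, nm.
#' @param n_sphere sphere refractive index: scalar, vector over the grid, or a
#'   function of wavelength.
#' @param n_medium medium refractive index: scalar, vector or function
#'   (default: the silicone medium dispersion, [siliglass_refractive_index()]).
#' @param csc scatterer volume fraction (dimensionless, e.g. 0.016); default 1
#'   returns the library values.
#' @param shell_um optional shell thickness, micrometres; with
#'   `shell_um > 0` and a user-supplied `n_shell` each bin is treated as a
#'   coated sphere of that shell ([mie_coated_sphere()]), `n_sphere` acting
#'   as the core index (real indices only in this mode).
#' @param n_shell shell refractive index (required when `shell_um > 0`).
#' @return A tibble with columns `lambda_nm`, `mus_cal` (1/cm per unit volume
#'   fraction), `mus` (1/cm at `csc`), `g`.
#' @export
distribution_scattering <- function(dist, lambda_nm,
                                    n_sphere = 1.59,
                                    n_medium = siliglass_refractive_index,
                                    csc = 1, shell_um = 0, n_shell = NULL) {
  stopifnot(inherits(dist, "sphere_distribution"))
  if (shell_um > 0 && is.null(n_shell)) {
    stop("n_shell must be supplied for the coated-sphere mode", call. = FALSE)
  }
  ns <- eval_index(n_sphere, lambda_nm)
  nm <- eval_index(n_medium, lambda_nm)
  mus_cal <- numeric(length(lambda_nm))
  gnum <- numeric(length(lambda_nm))
  for (k in seq_along(dist$radii_um)) {
    r <- dist$radii_um[k]
    phi <- dist$volume_fraction[k]
    if (phi == 0) next
    for (il in seq_along(lambda_nm)) {
      mi <- if (shell_um > 0) {
        # coated mode: listed radius is the outer radius, core shrinks
        core <- max(r - shell_um, 0.05 * r)
        mie_coated_single(2 * pi * core * nm[il] / (lambda_nm[il] / 1000),
                          2 * pi * r * nm[il] / (lambda_nm[il] / 1000),
                          ns[il] / nm[il], n_shell / nm[il])
      } else {
        mie_single(2 * pi * r * nm[il] / (lambda_nm[il] / 1000),
                   ns[il] / nm[il])
      }
      mus_i <- 3 * phi * mi[2] / (4 * r * 1e-4)   # radius um -> cm
      mus_cal[il] <- mus_cal[il] + mus_i
      gnum[il] <- gnum[il] + mus_i * mi[5]
    }
  }
  g <- ifelse(mus_cal > 0, gnum / mus_cal, 0)
  tibble::tibble(lambda_nm = as.numeric(lambda_nm), mus_cal = mus_cal,
                 mus = csc * mus_cal, g = g)
}

eval_index <- function(n, lambda_nm) {
  if (is.function(n)) n(lambda_nm)
  else if (length(n) == 1L) rep(n, length(lambda_nm))
  else { stopifnot(length(n) == length(lambda_nm)); n }
}

#' Lorenz-Mie efficiencies of a coated (core-shell) sphere
#'
#' Stratified-sphere partial-wave solution for a core of radius
#' `core_radius_um` covered by a concentric shell of thickness `shell_um`,
#' in a non-absorbing medium. Radial functions are evaluated through
#' half-integer-order Bessel functions; all indices must be real. With equal
#' core and shell indices the result reduces exactly to the homogeneous
#' sphere of the outer radius, which the tests assert.
#'
#' @param core_radius_um core radius, micrometres (> 0).
#' @param shell_um shell thickness, micrometres (>= 0; 0 falls back to the
#'   homogeneous sphere of the core index).
#' @param lambda_nm vacuum wavelength, nm (vectorized).
#' @param n_core,n_shell,n_medium real refractive indices.
#' @return A tibble like [mie_sphere()]'s.
#' @export
mie_coated_sphere <- function(core_radius_um, shell_um, lambda_nm,
                              n_core, n_shell, n_medium) {
  stopifnot(core_radius_um > 0, shell_um >= 0,
            Im(n_core) == 0, Im(n_shell) == 0, Im(n_medium) == 0)
  if (shell_um == 0) {
    return(mie_sphere(core_radius_um, lambda_nm, n_core, n_medium))
  }
  nm <- eval_index(n_medium, lambda_nm)
  res <- lapply(seq_along(lambda_nm), function(i) {
    k <- 2 * pi * nm[i] / (lambda_nm[i] / 1000)
    mie_coated_single(k * core_radius_um,
                      k * (core_radius_um + shell_um),
                      n_core / nm[i], n_shell / nm[i])
  })
  out <- do.call(rbind, res)
  tibble::tibble(lambda_nm = as.numeric(lambda_nm),
                 x = out[, 1], qsca = out[, 2], qext = out[, 3],
                 qabs = out[, 4], g = out[, 5])
}

# real-index coated sphere: core size parameter x, outer size parameter y,
# relative indices m1 (core), m2 (shell)
mie_coated_single <- function(x, y, m1, m2) {
  nmax <- ceiling(y + 4.05 * y^(1 / 3) + 2)
  n <- seq_len(nmax)
  psi <- function(nn, z) sqrt(pi * z / 2) * besselJ(z, nn + 0.5)
  chi <- function(nn, z) -sqrt(pi * z / 2) * besselY(z, nn + 0.5)
  dfun <- function(f, nn, z) f(nn - 1, z) - nn / z * f(nn, z)
  psi_y <- psi(n, y); dpsi_y <- dfun(psi, n, y)
  chi_y <- chi(n, y); dchi_y <- dfun(chi, n, y)
  xi_y <- complex(real = psi_y, imaginary = -chi_y)
  dxi_y <- complex(real = dpsi_y, imaginary = -dchi_y)
  p_m1x <- psi(n, m1 * x); dp_m1x <- dfun(psi, n, m1 * x)
  p_m2x <- psi(n, m2 * x); dp_m2x <- dfun(psi, n, m2 * x)
  c_m2x <- chi(n, m2 * x); dc_m2x <- dfun(chi, n, m2 * x)
  p_m2y <- psi(n, m2 * y); dp_m2y <- dfun(psi, n, m2 * y)
  c_m2y <- chi(n, m2 * y); dc_m2y <- dfun(chi, n, m2 * y)
  A <- (m2 * p_m2x * dp_m1x - m1 * dp_m2x * p_m1x) /
    (m2 * c_m2x * dp_m1x - m1 * dc_m2x * p_m1x)
  B <- (m2 * p_m1x * dp_m2x - m1 * p_m2x * dp_m1x) /
    (m2 * dc_m2x * p_m1x - m1 * dp_m1x * c_m2x)
  ua <- dp_m2y - A * dc_m2y
  va <- p_m2y - A * c_m2y
  ub <- dp_m2y - B * dc_m2y
  vb <- p_m2y - B * c_m2y
  a <- (psi_y * ua - m2 * dpsi_y * va) / (xi_y * ua - m2 * dxi_y * va)
  b <- (m2 * psi_y * ub - dpsi_y * vb) / (m2 * xi_y * ub - dxi_y * vb)
  qsca <- (2 / y^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  qext <- (2 / y^2) * sum((2 * n + 1) * Re(a + b))
  n1 <- n[-nmax]
  gsum <- sum(n1 * (n1 + 2) / (n1 + 1) *
                Re(a[n1] * Conj(a[n1 + 1]) + b[n1] * Conj(b[n1 + 1]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- if (qsca > 0) 4 / y^2 * gsum / qsca else 0
  c(y, qsca, qext, max(qext - qsca, 0), g)
}
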