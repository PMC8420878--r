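# Independent oracles used across the suite.

# Lorenz-Mie via half-integer-order Bessel functions from base R
# (besselJ/besselY), upward derivative recurrences, real relative index.
# Algorithmically independent of the package's downward-recurrence
# implementation.
mie_oracle <- function(x, m) {
  stopifnot(is.finite(x), x > 0, Im(m) == 0)
  nmax <- ceiling(x + 4.05 * x^(1 / 3) + 2)
  n <- seq_len(nmax)
  psi <- function(nn, z) sqrt(pi * z / 2) * besselJ(z, nn + 0.5)
  chi <- function(nn, z) -sqrt(pi * z / 2) * besselY(z, nn + 0.5)
  psi_x <- psi(n, x); psi_xm1 <- psi(n - 1, x)
  chi_x <- chi(n, x); chi_xm1 <- chi(n - 1, x)
  xi_x <- complex(real = psi_x, imaginary = -chi_x)
  xi_xm1 <- complex(real = psi_xm1, imaginary = -chi_xm1)
  dpsi_x <- psi_xm1 - n / x * psi_x
  dxi_x <- xi_xm1 - n / x * xi_x
  mx <- m * x
  psi_mx <- psi(n, mx); psi_mxm1 <- psi(n - 1, mx)
  dpsi_mx <- psi_mxm1 - n / mx * psi_mx
  a <- (m * psi_mx * dpsi_x - psi_x * dpsi_mx) /
    (m * psi_mx * dxi_x - xi_x * dpsi_mx)
  b <- (psi_mx * dpsi_x - m * psi_x * dpsi_mx) /
    (psi_mx * dxi_x - m * xi_x * dpsi_mx)
  qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  qext <- (2 / x^2) * sum((2 * n + 1) * Re(a + b))
  n1 <- n[-nmax]
  gsum <- sum(n1 * (n1 + 2) / (n1 + 1) *
                Re(a[n1] * Conj(a[n1 + 1]) + b[n1] * Conj(b[n1 + 1]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  list(qsca = qsca, qext = qext, g = 4 / x^2 * gsum / qsca)
}

# Rayleigh-limit closed form for the scattering efficiency
rayleigh_qsca <- function(x, m) {
  8 / 3 * x^4 * Mod((m^2 - 1) / (m^2 + 2))^2
}
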