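#' Conical-flux quadrature for the adding-doubling solver
#'
#' Builds the M-cone angular quadrature of the cosine interval (0, 1]. A
#' Gauss-Radau rule with fixed right endpoint is used so that `mu = 1` is a
#' node and collimated normal illumination maps exactly onto a cone. For a
#' refractive-index-mismatched slab (`n_rel > 1`) the interval is split at
#' the critical cosine `mu_c = sqrt(1 - 1/n_rel^2)`: half the cones sample
#' the totally internally reflected range `(0, mu_c)` (Gauss-Legendre), half
#' the escaping range `[mu_c, 1]` (Gauss-Radau including 1).
#'
#' @param M number of cones (default 20).
#' @param n_rel slab refractive index relative to the outside (default 1).
#' @return An object of class `ad_quadrature` with nodes `mu` (ascending,
#'   last = 1), weights `w` (summing to 1), `M` and `n_rel`.
#' @export
ad_quadrature <- function(M = 20, n_rel = 1) {
  stopifnot(M >= 4)
  if (abs(n_rel - 1) < 1e-9) {
    q <- radau_right(M, 0, 1)
  } else {
    mu_c <- sqrt(1 - 1 / n_rel^2)
    m1 <- M %/% 2L
    g1 <- gauss_interval(m1, 0, mu_c)
    g2 <- radau_right(M - m1, mu_c, 1)
    q <- list(x = c(g1$x, g2$x), w = c(g1$w, g2$w))
  }
  structure(list(mu = q$x, w = q$w, M = M, n_rel = n_rel),
            class = "ad_quadrature")
}

gauss_from_jacobi <- function(alpha, beta) {
  n <- length(alpha)
  J <- diag(alpha, n)
  if (n > 1) {
    off <- sqrt(beta[2:n])
    J[cbind(1:(n - 1), 2:n)] <- off
    J[cbind(2:n, 1:(n - 1))] <- off
  }
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = beta[1] * e$vectors[1, ord]^2)
}

legendre_rc <- function(n) {
  k <- seq_len(n - 1)
  list(alpha = rep(0, n), beta = c(2, k^2 / (4 * k^2 - 1)))
}

# Gauss-Radau on [-1, 1] with fixed node at -1 (Golub-Welsch with the last
# recurrence coefficient modified, Gautschi's construction)
radau_left_ref <- function(n) {
  if (n == 1) return(list(x = -1, w = 2))
  rc <- legendre_rc(n)
  x0 <- -1
  pm1 <- 0; p <- 1
  for (k in 0:(n - 2)) {
    pnew <- (x0 - rc$alpha[k + 1]) * p - (if (k == 0) 0 else rc$beta[k + 1]) * pm1
    pm1 <- p; p <- pnew
  }
  rc$alpha[n] <- x0 - rc$beta[n] * pm1 / p
  gauss_from_jacobi(rc$alpha, rc$beta)
}

radau_right <- function(n, a, b) {
  q <- radau_left_ref(n)
  x <- rev(-q$x)
  w <- rev(q$w)
  list(x = a + (b - a) * (x + 1) / 2, w = w * (b - a) / 2)
}

gauss_interval <- function(n, a, b) {
  rc <- legendre_rc(n)
  q <- gauss_from_jacobi(rc$alpha, rc$beta)
  list(x = a + (b - a) * (q$x + 1) / 2, w = q$w * (b - a) / 2)
}

#' Henyey-Greenstein redistribution matrices between quadrature cones
#'
#' Azimuthally averaged Henyey-Greenstein phase function evaluated between
#' all cone pairs via the Legendre addition theorem, for the same-hemisphere
#' (`hpp`) and opposite-hemisphere (`hpm`) halves, symmetrically renormalized
#' so that every (weighted) row integrates to one and a conservative layer
#' conserves energy exactly.
#'
#' @param g anisotropy, `0 <= g < 1`.
#' @param scheme an [ad_quadrature()].
#' @return List with matrices `hpp` and `hpm` (`M x M`).
#' @export
hg_redistribution <- function(g, scheme) {
  stopifnot(inherits(scheme, "ad_quadrature"))
  if (g < 0 || g >= 1) stop("g must be in [0, 1)", call. = FALSE)
  cpp_hg_matrix(scheme$mu, scheme$w, g)
}

#' Reflection and transmission operators of a homogeneous layer
#'
#' Doubles an optically thin starting layer (first-order in its thickness,
#' exact ballistic attenuation) up to the layer's full optical thickness.
#' The returned matrices act on per-cone flux vectors.
#'
#' @param mua,mus 1/cm; `g` anisotropy; `thickness_cm` cm.
#' @param scheme an [ad_quadrature()].
#' @return List with flux-basis operators `R` and `T` and the optical
#'   thickness `tau`.
#' @export
layer_rt <- function(mua, mus, g, thickness_cm, scheme) {
  stopifnot(inherits(scheme, "ad_quadrature"))
  mut <- mua + mus
  tau <- mut * thickness_cm
  albedo <- if (mut > 0) mus / mut else 0
  h <- hg_redistribution(g, scheme)
  ops <- cpp_layer_ops(scheme$mu, scheme$w, h$hpp, h$hpm, albedo, tau)
  ops$tau <- tau
  ops
}

#' Total reflectance/transmittance of a layer stack with boundaries
#'
#' Combines the layer operators with Fresnel boundary operators at the top
#' and bottom interface (per-cone reflectances, total internal reflection
#' below the critical cosine) using the adding equations, and illuminates
#' the stack with a collimated normal beam. The collimated specular
#' reflection at the top interface is excluded from `r_total` (cross-polarized
#' detection); it is reported separately as `r_specular`.
#'
#' @param layers list of layers, each a list with scalars `mua`, `mus`, `g`,
#'   `thickness_cm`.
#' @param n_slab slab refractive index (relative to `n_outside`).
#' @param n_outside outside medium index (default 1, air).
#' @param M number of cones.
#' @return An `rt_result`: list with `r_total`, `t_total`, `a_total`,
#'   `r_specular`.
#' @export
ad_rt <- function(layers, n_slab, n_outside = 1, M = 20) {
  n_rel <- n_slab / n_outside
  scheme <- ad_quadrature(M, n_rel)
  hpp <- list(); hpm <- list()
  albedo <- numeric(length(layers)); tau <- numeric(length(layers))
  for (k in seq_along(layers)) {
    ly <- layers[[k]]
    h <- hg_redistribution(ly$g, scheme)
    hpp[[k]] <- h$hpp; hpm[[k]] <- h$hpm
    mut <- ly$mua + ly$mus
    albedo[k] <- if (mut > 0) ly$mus / mut else 0
    tau[k] <- mut * ly$thickness_cm
  }
  v <- cpp_ad_solve(scheme$mu, scheme$w, hpp, hpm, albedo, tau, n_rel)
  structure(list(r_total = v[1], t_total = v[2], a_total = v[3],
                 r_specular = v[4]),
            class = "rt_result")
}

#' @export
print.rt_result <- function(x, ...) {
  cat(sprintf("<rt_result> R = %.6f, T = %.6f, A = %.6f (specular %.4f excluded)\n",
              x$r_total, x$t_total, x$a_total, x$r_specular))
  invisible(x)
}

# Per-wavelength cache of quadrature + redistribution matrices for a slab
# model family (fixed wavelength grid, n(lambda) and g(lambda) per layer).
ad_cache <- function(lambda_nm, n_slab, g_layers, M = 20) {
  nlam <- length(lambda_nm)
  g_layers <- as.matrix(g_layers)
  if (nrow(g_layers) == 1L) {
    g_layers <- g_layers[rep(1L, nlam), , drop = FALSE]
  }
  nlay <- ncol(g_layers)
  mu_mat <- matrix(0, nlam, M); w_mat <- matrix(0, nlam, M)
  hpp <- array(0, c(M, M, nlam * nlay))
  hpm <- array(0, c(M, M, nlam * nlay))
  for (l in seq_len(nlam)) {
    sch <- ad_quadrature(M, n_slab[l])
    mu_mat[l, ] <- sch$mu; w_mat[l, ] <- sch$w
    for (k in seq_len(nlay)) {
      h <- cpp_hg_matrix(sch$mu, sch$w, g_layers[l, k])
      hpp[, , (l - 1) * nlay + k] <- h$hpp
      hpm[, , (l - 1) * nlay + k] <- h$hpm
    }
  }
  list(lambda_nm = lambda_nm, mu = mu_mat, w = w_mat, hpp = hpp, hpm = hpm,
       n_rel = n_slab, M = M, nlay = nlay)
}

#' Forward diffuse-reflectance spectrum of a slab model
#'
#' Runs the adding-doubling solver at every wavelength of the slab model's
#' grid. A quadrature/redistribution cache may be supplied to amortize setup
#' across repeated evaluations (as the per-pixel fits do).
#'
#' @param slab a [build_slab()] result.
#' @param M number of cones (default 20).
#' @param cache optional cache from a previous call (internal use).
#' @return A tibble with columns `lambda_nm`, `r_total`, `t_total`,
#'   `a_total`, `r_specular`.
#' @export
forward_spectrum <- function(slab, M = 20, cache = NULL) {
  stopifnot(inherits(slab, "slab_model"))
  nlay <- length(slab$layers)
  n_slab <- slab$layers[[1]]$n / slab$n_outside
  if (is.null(cache)) {
    g_layers <- sapply(slab$layers, function(l) l$g)
    cache <- ad_cache(slab$lambda_nm, n_slab, g_layers, M)
  }
  mut <- sapply(slab$layers, function(l) l$mua + l$mus)
  albedo <- sapply(slab$layers, function(l) {
    m <- l$mua + l$mus
    ifelse(m > 0, l$mus / m, 0)
  })
  tau <- sweep(as.matrix(mut), 2, sapply(slab$layers, `[[`, "thickness_cm"), `*`)
  out <- cpp_ad_spectrum(cache$mu, cache$w, cache$hpp, cache$hpm,
                         as.matrix(albedo), tau, n_slab)
  tibble::tibble(lambda_nm = slab$lambda_nm,
                 r_total = out[, 1], t_total = out[, 2],
                 a_total = out[, 3], r_specular = out[, 4])
}
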