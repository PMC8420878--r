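#' Forward model factory for spectral fitting
#'
#' Builds a reusable forward-model object for the one-layer phantom or the
#' two-layer skin model on a fixed wavelength grid. All quantities that do
#' not depend on the free parameters (extinction tables resampled to the
#' grid, the Mie scattering library, refractive-index dispersion, angular
#' quadrature and redistribution matrices) are precomputed once, so repeated
#' evaluations inside the per-pixel fits only update absorption/scattering
#' and run the adding-doubling recursion.
#'
#' Free parameters: phantom `(cabs_pct, csc_pct)`; skin
#' `(fmel, fhb, fhbo2, fcyt_red, fcyt_ox, a)` with the customary bounds from
#' [skin_bounds()].
#'
#' @param model `"phantom"` or `"skin"`.
#' @param lambda_nm wavelength grid (default [default_grid()]).
#' @param M number of quadrature cones.
#' @param tables optional tables ([phantom_tables()] / [chromophore_tables()]).
#' @param dist optional [sphere_distribution()] (phantom model).
#' @return An object of class `forward_model` with elements `par_names`,
#'   `lower`, `upper`, and `forward(par)` returning the reflectance vector.
#' @export
forward_model <- function(model = c("phantom", "skin"),
                          lambda_nm = default_grid(), M = 20,
                          tables = NULL, dist = NULL) {
  model <- match.arg(model)
  if (model == "phantom") {
    if (is.null(tables)) tables <- phantom_tables()
    if (is.null(dist)) dist <- read_sphere_distribution()
    mu_ab <- resample_table(tables$medium, lambda_nm)
    mu_abs <- resample_table(tables$pigment, lambda_nm)
    lib <- distribution_scattering(dist, lambda_nm)
    n_slab <- siliglass_refractive_index(lambda_nm)
    cache <- ad_cache(lambda_nm, n_slab, matrix(lib$g, ncol = 1), M)
    thick <- phantom_recipe$layer_thickness_cm
    fwd <- function(par) {
      cabs <- par[1] / 100; csc <- par[2] / 100
      mua <- (1 - cabs) * mu_ab + cabs * mu_abs / phantom_recipe$dilution_constant
      mus <- csc * lib$mus_cal
      mut <- mua + mus
      out <- cpp_ad_spectrum(cache$mu, cache$w, cache$hpp, cache$hpm,
                             matrix(ifelse(mut > 0, mus / mut, 0), ncol = 1),
                             matrix(mut * thick, ncol = 1), n_slab)
      out[, 1]
    }
    obj <- list(model = model, lambda_nm = lambda_nm,
                par_names = c("cabs_pct", "csc_pct"),
                lower = c(0.1, 0.1), upper = c(45, 10),
                forward = fwd, cache = cache)
  } else {
    if (is.null(tables)) tables <- chromophore_tables()
    ext <- list(hb = resample_table(tables$hb, lambda_nm),
                hbo2 = resample_table(tables$hbo2, lambda_nm),
                bil = resample_table(tables$bilirubin, lambda_nm),
                red = resample_table(tables$cyt_red, lambda_nm),
                ox = resample_table(tables$cyt_ox, lambda_nm))
    mel <- melanin_mua(lambda_nm)
    n_slab <- skin_refractive_index(lambda_nm)
    g <- skin_constants$g
    cache <- ad_cache(lambda_nm, n_slab, matrix(g, 1, 2), M)
    lamb_pow <- (lambda_nm / 500)^(-skin_constants$b)
    bnd <- skin_bounds()
    fwd <- function(par, fbil = 0) {
      mua_epi <- par[1] / 100 * mel + skin_constants$baseline_mua
      mua_der <- par[2] / 100 * ext$hb + par[3] / 100 * ext$hbo2 +
        fbil * ext$bil + par[4] * ext$red + par[5] * ext$ox +
        skin_constants$baseline_mua
      mus <- par[6] * lamb_pow / (1 - g)
      mut_epi <- mua_epi + mus
      mut_der <- mua_der + mus
      albedo <- cbind(mus / mut_epi, mus / mut_der)
      tau <- cbind(mut_epi * skin_constants$d_epi_cm,
                   mut_der * skin_constants$d_derm_cm)
      out <- cpp_ad_spectrum(cache$mu, cache$w, cache$hpp, cache$hpm,
                             albedo, tau, n_slab)
      out[, 1]
    }
    obj <- list(model = model, lambda_nm = lambda_nm,
                par_names = bnd$param, lower = bnd$lower, upper = bnd$upper,
                forward = fwd, cache = cache)
  }
  class(obj) <- "forward_model"
  obj
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model> %s, %d wavelengths, parameters: %s\n",
              x$model, length(x$lambda_nm), paste(x$par_names, collapse = ", ")))
  invisible(x)
}
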