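#' Per-layer optical properties
#'
#' One slab layer: absorption and scattering coefficients per wavelength,
#' anisotropy, refractive index and thickness, as consumed by the
#' adding-doubling solver.
#'
#' @param lambda_nm wavelength grid, nm.
#' @param mua,mus 1/cm per wavelength (scalars recycled).
#' @param g anisotropy in `[0, 1)` (scalar or per wavelength).
#' @param n refractive index (>= 1; scalar or per wavelength).
#' @param thickness_cm layer thickness, cm (> 0).
#' @return An object of class `layer_properties`.
#' @export
layer_properties <- function(lambda_nm, mua, mus, g, n, thickness_cm) {
  nl <- length(lambda_nm)
  rec <- function(x) if (length(x) == 1L) rep(x, nl) else x
  mua <- rec(mua); mus <- rec(mus); g <- rec(g); n <- rec(n)
  stopifnot(length(mua) == nl, length(mus) == nl, length(g) == nl,
            length(n) == nl)
  if (any(mua < 0) || any(mus < 0)) stop("mua and mus must be >= 0", call. = FALSE)
  if (any(g < 0) || any(g >= 1)) stop("g must be in [0, 1)", call. = FALSE)
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (thickness_cm <= 0) stop("thickness must be > 0", call. = FALSE)
  structure(list(lambda_nm = as.numeric(lambda_nm), mua = mua, mus = mus,
                 g = g, n = n, thickness_cm = thickness_cm),
            class = "layer_properties")
}

#' Build a slab model from phantom or skin parameters
#'
#' For the phantom model: a single 2-cm layer with the silicone Sellmeier
#' index, pigment/medium absorption and Mie-library scattering. For the skin
#' model: a 100-um epidermis over a 1-cm dermis (a very thick, essentially
#' non-transmitting layer), both with the skin dispersion and `g = 0.82`.
#'
#' @param model `"phantom"` or `"skin"`.
#' @param params a [phantom_params()] or [skin_params()].
#' @param lambda_nm wavelength grid, nm.
#' @param scattering_library optional precomputed tibble from
#'   [distribution_scattering()] (phantom model); computed on demand
#'   otherwise.
#' @param tables optional chromophore/phantom tables.
#' @return An object of class `slab_model`: list of [layer_properties()] plus
#'   the outside refractive index.
#' @export
build_slab <- function(model = c("phantom", "skin"), params, lambda_nm,
                       scattering_library = NULL, tables = NULL) {
  model <- match.arg(model)
  if (model == "phantom") {
    stopifnot(inherits(params, "phantom_params") || is.list(params))
    if (is.null(tables)) tables <- phantom_tables()
    if (is.null(scattering_library)) {
      scattering_library <- distribution_scattering(
        read_sphere_distribution(), lambda_nm)
    }
    mua <- phantom_mua(params, tables, lambda_nm)
    mus <- params$csc_pct / 100 * scattering_library$mus_cal
    layers <- list(layer_properties(
      lambda_nm, mua, mus, scattering_library$g,
      siliglass_refractive_index(lambda_nm),
      phantom_recipe$layer_thickness_cm))
  } else {
    stopifnot(inherits(params, "skin_params") || is.list(params))
    if (is.null(tables)) tables <- chromophore_tables()
    n <- skin_refractive_index(lambda_nm)
    mus <- skin_mus_prime(params$a, lambda_nm) / (1 - skin_constants$g)
    layers <- list(
      layer_properties(lambda_nm, epidermis_mua(params$fmel, lambda_nm),
                       mus, skin_constants$g, n, skin_constants$d_epi_cm),
      layer_properties(lambda_nm, dermis_mua(params, tables, lambda_nm),
                       mus, skin_constants$g, n, skin_constants$d_derm_cm)
    )
  }
  structure(list(layers = layers, lambda_nm = as.numeric(lambda_nm),
                 n_outside = 1.0, model = model),
            class = "slab_model")
}

#' @export
print.slab_model <- function(x, ...) {
  cat(sprintf("<slab_model> %s, %d layer(s), %d wavelengths (%.0f-%.0f nm)\n",
              x$model, length(x$layers), length(x$lambda_nm),
              min(x$lambda_nm), max(x$lambda_nm)))
  for (k in seq_along(x$layers)) {
    ly <- x$layers[[k]]
    cat(sprintf("  layer %d: d = %.4g cm, mua in [%.3g, %.3g], mus in [%.3g, %.3g] 1/cm\n",
                k, ly$thickness_cm, min(ly$mua), max(ly$mua),
                min(ly$mus), max(ly$mus)))
  }
  invisible(x)
}
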