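#' Phantom recipe constants
#'
#' Constants of the silicone phantom recipe: the pigment pre-dilution ratio in
#' silicone part A (1:2272), and the dilution-mismatch constant 0.13246 that
#' rescales the tabulated pigment absorption (measured at mass fraction
#' 5.83e-5) to the diluted-absorber volume-fraction convention of the
#' absorption model.
#'
#' @format A list with elements `dilution_ratio` (2272), `dilution_constant`
#'   (0.13246), `wall_loss_g` (1), `layer_thickness_cm` (2).
#' @export
phantom_recipe <- list(
  dilution_ratio = 2272,
  dilution_constant = 0.13246,
  wall_loss_g = 1,
  layer_thickness_cm = 2
)

#' Phantom composition parameters
#'
#' Volume fractions (in percent) of the diluted absorber and the scatterer in
#' a silicone phantom. The polymerized-silicone fraction is the complement of
#' the absorber fraction.
#'
#' @param cabs_pct diluted-absorber volume fraction, percent (0-100).
#' @param csc_pct scatterer volume fraction, percent (0-100).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(cabs_pct, csc_pct) {
  stopifnot(cabs_pct >= 0, cabs_pct <= 100, csc_pct >= 0, csc_pct <= 100)
  structure(list(cabs_pct = cabs_pct, csc_pct = csc_pct),
            class = "phantom_params")
}

#' Component masses for a phantom preparation
#'
#' Given the target diluted-absorber and scatterer volume fractions (as
#' fractions, not percent) and the mass of silicone part A, returns the
#' masses of diluted absorber, scatterer and part B:
#' `mabs = 2 Cabs mA / (1 - 2 Cabs)`, `msc = 2 Csc (mA + mabs)`,
#' `mB = mA + mabs - msc`. Optionally applies the empirical wall-loss
#' adjustment (part B increased by 1 g, scatterer rescaled to keep the target
#' concentration).
#'
#' @param cabs,csc volume fractions (dimensionless; `cabs < 0.5`).
#' @param mA mass of part A, grams.
#' @param wall_loss apply the +1 g wall-loss adjustment (default FALSE).
#' @return A tibble with columns `mabs_g`, `msc_g`, `mB_g`.
#' @examples
#' phantom_masses(0.037, 0.016, 50)
#' @export
phantom_masses <- function(cabs, csc, mA, wall_loss = FALSE) {
  stopifnot(cabs >= 0, csc >= 0, mA > 0)
  if (cabs >= 0.5) stop("cabs must be below 0.5 (pole of the mass relation)",
                        call. = FALSE)
  mabs <- 2 * cabs * mA / (1 - 2 * cabs)
  msc <- 2 * csc * (mA + mabs)
  mB <- mA + mabs - msc
  if (wall_loss) {
    mB <- mB + phantom_recipe$wall_loss_g
    # keep the scatterer concentration at its target for the larger batch
    msc <- 2 * csc * (mA + mabs + phantom_recipe$wall_loss_g)
  }
  tibble::tibble(mabs_g = mabs, msc_g = msc, mB_g = mB)
}

#' Refractive index of the polymerized silicone medium
#'
#' One-term Sellmeier dispersion of the phantom substrate:
#' `n^2 = 1 + 0.95007197 lr^2 / (lr^2 - 0.05943376)` with
#' `lr = lambda / 436.4 nm`.
#'
#' @param lambda_nm wavelength, nm (vectorized).
#' @return Refractive index values.
#' @examples
#' siliglass_refractive_index(436.4)  # ~1.41779
#' @export
siliglass_refractive_index <- function(lambda_nm) {
  lr2 <- (lambda_nm / 436.4)^2
  if (any(abs(lr2 - 0.05943376) < 1e-12)) {
    stop("wavelength at the Sellmeier pole", call. = FALSE)
  }
  sqrt(1 + 0.95007197 * lr2 / (lr2 - 0.05943376))
}

#' Phantom absorption coefficient
#'
#' `mua = CAB * muAB + Cabs * muabs / 0.13246`, where `CAB = 1 - Cabs` is the
#' polymerized-silicone volume fraction, `muAB` the absorption of the clear
#' medium and `muabs` the tabulated absorption of the diluted pigment. The
#' denominator rescales for the mismatch between the dilution used when the
#' pigment absorption was measured and the 1:2272 pre-dilution of the recipe.
#'
#' @param params a [phantom_params()] (percent convention) or a plain list
#'   with `cabs_pct`.
#' @param tables phantom absorption tables from [phantom_tables()].
#' @param lambda_nm wavelength grid, nm (must lie within table coverage).
#' @param subtract_scatterer also subtract the scatterer volume fraction from
#'   the medium fraction (`CAB = 1 - Cabs - Csc`); default FALSE.
#' @return Numeric vector `mua` in 1/cm.
#' @export
phantom_mua <- function(params, tables = phantom_tables(), lambda_nm,
                        subtract_scatterer = FALSE) {
  cabs <- params$cabs_pct / 100
  cab <- 1 - cabs - if (subtract_scatterer) params$csc_pct / 100 else 0
  mu_ab <- resample_table(tables$medium, lambda_nm)
  mu_abs <- resample_table(tables$pigment, lambda_nm)
  cab * mu_ab + cabs * mu_abs / phantom_recipe$dilution_constant
}
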