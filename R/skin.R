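#' Two-layer skin model parameters
#'
#' Free parameters of the two-layer skin model and their customary bounds:
#' melanin volume fraction `fmel` (%), deoxy- and oxyhemoglobin volume
#' fractions `fhb`, `fhbo2` (%, whole-blood convention), reduced and oxidized
#' cytochrome c oxidase concentrations `fcyt_red`, `fcyt_ox` (mM), and the
#' reduced scattering coefficient at 500 nm `a` (1/cm). Bilirubin `fbil` (mM)
#' is carried by the model but fixed (default 0): it is part of the dermis
#' absorption sum yet not a free fit parameter. The scattering power
#' `b = 1.27`, anisotropy `g = 0.82`, epidermis thickness 100 um and dermis
#' thickness 1 cm are fixed model constants.
#'
#' @param fmel,fhb,fhbo2 percent.
#' @param fcyt_red,fcyt_ox mM.
#' @param a 1/cm at 500 nm.
#' @param fbil mM (fixed parameter, default 0).
#' @return An object of class `skin_params`.
#' @export
skin_params <- function(fmel = 1.5, fhb = 1, fhbo2 = 3, fcyt_red = 0.3,
                        fcyt_ox = 0.3, a = 30, fbil = 0) {
  structure(list(fmel = fmel, fhb = fhb, fhbo2 = fhbo2,
                 fcyt_red = fcyt_red, fcyt_ox = fcyt_ox, a = a, fbil = fbil),
            class = "skin_params")
}

#' Bounds of the six free skin parameters
#'
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
skin_bounds <- function() {
  tibble::tibble(
    param = c("fmel", "fhb", "fhbo2", "fcyt_red", "fcyt_ox", "a"),
    lower = c(0.1, 0.1, 0.1, 0.1, 0.1, 20),
    upper = c(15, 20, 20, 2, 2, 50)
  )
}

# fixed model constants
skin_constants <- list(b = 1.27, g = 0.82, d_epi_cm = 0.01, d_derm_cm = 1,
                       baseline_mua = 0.25)

#' Epidermis absorption coefficient
#'
#' `mua_epi = fmel * mua_mel + 0.25 1/cm` with the melanin power law
#' `mua_mel = 6.6e11 * (lambda/nm)^-3.33` 1/cm; 0.25 1/cm is the baseline
#' absorption of bloodless skin.
#'
#' @param fmel melanin volume fraction, percent.
#' @param lambda_nm wavelength grid, nm.
#' @return `mua` in 1/cm.
#' @examples
#' melanin_mua(500)  # ~678 1/cm
#' @export
epidermis_mua <- function(fmel, lambda_nm) {
  stopifnot(fmel >= 0)
  fmel / 100 * melanin_mua(lambda_nm) + skin_constants$baseline_mua
}

#' @rdname epidermis_mua
#' @export
melanin_mua <- function(lambda_nm) 6.6e11 * lambda_nm^-3.33

#' Dermis absorption coefficient
#'
#' Sum of the blood, bilirubin and cytochrome c oxidase contributions plus
#' the 0.25 1/cm baseline:
#' `mua_der = fhb mua_Hb + fhbo2 mua_HbO2 + fbil mua_bil + fcyt_red mua_red +
#' fcyt_ox mua_ox + 0.25`. Hemoglobin fractions are volume fractions (%,
#' whole-blood extinction); cytochromes and bilirubin are mM with millimolar
#' extinction, mirroring the mixed units of the customary model. The total
#' blood volume fraction is `fhb + fhbo2`.
#'
#' @param params a [skin_params()].
#' @param tables chromophore tables from [chromophore_tables()].
#' @param lambda_nm wavelength grid, nm.
#' @return `mua` in 1/cm.
#' @export
dermis_mua <- function(params, tables = chromophore_tables(), lambda_nm) {
  params$fhb / 100 * resample_table(tables$hb, lambda_nm) +
    params$fhbo2 / 100 * resample_table(tables$hbo2, lambda_nm) +
    params$fbil * resample_table(tables$bilirubin, lambda_nm) +
    params$fcyt_red * resample_table(tables$cyt_red, lambda_nm) +
    params$fcyt_ox * resample_table(tables$cyt_ox, lambda_nm) +
    skin_constants$baseline_mua
}

#' Skin reduced scattering and refractive index
#'
#' Reduced scattering power-law ansatz `mus' = a (lambda/500 nm)^-b` with
#' `b = 1.27`; the scattering coefficient follows from the similarity
#' relation `mus = mus' / (1 - g)` with `g = 0.82`. The refractive index of
#' both layers is the Cauchy-type dispersion
#' `n = 1.309 + 4.36e2/lambda^2 + 1.6065e9/lambda^4 - 1.12811e14/lambda^6`
#' (lambda in nm).
#'
#' @param a reduced scattering at 500 nm, 1/cm.
#' @param lambda_nm wavelength grid, nm.
#' @param b scattering power (default 1.27).
#' @return `skin_mus_prime()`: `mus'` in 1/cm; `skin_refractive_index()`: n.
#' @export
skin_mus_prime <- function(a, lambda_nm, b = skin_constants$b) {
  stopifnot(a > 0)
  a * (lambda_nm / 500)^(-b)
}

#' @rdname skin_mus_prime
#' @export
skin_refractive_index <- function(lambda_nm) {
  1.309 + 4.36e2 * lambda_nm^-2 + 1.6065e9 * lambda_nm^-4 -
    1.12811e14 * lambda_nm^-6
}
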