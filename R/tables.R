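#' Bundled chromophore extinction tables (synthetic)
#'
#' Loads the bundled absorption tables for deoxyhemoglobin, oxyhemoglobin
#' (whole-blood convention: 1/cm at 100 % blood volume fraction), bilirubin,
#' and reduced/oxidized cytochrome c oxidase (1/cm per mM). The bundled
#' tables are synthetic constructions: smooth band models carrying the known
#' qualitative features of the real compilations (Soret and Q bands,
#' isosbestic structure, relative magnitudes), covering 400-750 nm. Their
#' provenance is recorded in the attribute `"provenance"`.
#'
#' @param path CSV path; default: the bundled
#'   `chromophores_synthetic.csv` (long format: `chromophore`,
#'   `wavelength_nm`, `value`, `units`).
#' @return A named list of tables, each a tibble `(wavelength_nm, value)`,
#'   with names `hb`, `hbo2`, `bilirubin`, `cyt_red`, `cyt_ox`.
#' @export
chromophore_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chromophores_synthetic.csv",
                        package = "hsicurve", mustWork = TRUE)
  }
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$chromophore), function(d) {
    tibble::tibble(wavelength_nm = d$wavelength_nm, value = d$value,
                   units = d$units[1])
  })
  out <- out[c("hb", "hbo2", "bilirubin", "cyt_red", "cyt_ox")]
  attr(out, "provenance") <- "synthetic band models (see data-raw/make_tables.R)"
  out
}

#' Bundled phantom absorption tables (synthetic)
#'
#' Absorption coefficient of the clear polymerized silicone medium and of the
#' diluted pigment (at the measurement mass fraction 5.83e-5), 1/cm, over
#' 400-750 nm. Synthetic stand-ins calibrated so that the recipe
#' concentration range maps to absorption coefficients of about 0.1-1.1 1/cm.
#'
#' @param path CSV path; default: bundled `phantom_absorption_synthetic.csv`
#'   (columns `wavelength_nm`, `medium`, `pigment`).
#' @return A list of tibbles `medium` and `pigment`, each
#'   `(wavelength_nm, value)`.
#' @export
phantom_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phantom_absorption_synthetic.csv",
                        package = "hsicurve", mustWork = TRUE)
  }
  df <- utils::read.csv(path)
  list(
    medium = tibble::tibble(wavelength_nm = df$wavelength_nm,
                            value = df$medium),
    pigment = tibble::tibble(wavelength_nm = df$wavelength_nm,
                             value = df$pigment)
  )
}

#' Resample a tabulated spectrum onto a wavelength grid
#'
#' Linear interpolation; the tables are dense and smooth so linear error is
#' negligible. Requesting wavelengths outside the table coverage is an error.
#'
#' @param table a tibble with `wavelength_nm` and `value`.
#' @param lambda_nm target grid, nm.
#' @return Numeric vector of interpolated values.
#' @export
resample_table <- function(table, lambda_nm) {
  rng <- range(table$wavelength_nm)
  if (any(lambda_nm < rng[1] - 1e-9 | lambda_nm > rng[2] + 1e-9)) {
    stop(sprintf("requested wavelengths outside table coverage [%.1f, %.1f] nm",
                 rng[1], rng[2]), call. = FALSE)
  }
  stats::approx(table$wavelength_nm, table$value, xout = lambda_nm,
                rule = 1)$y
}

#' Default fitting wavelength grid
#'
#' 430 to 700 nm in 5-nm steps (the range where visible chromophore
#' contrast is strongest and the polarizer pair is effective); the upper end
#' is configurable up to table coverage.
#'
#' @param from,to,by grid limits and step in nm.
#' @return Numeric vector of wavelengths.
#' @export
default_grid <- function(from = 430, to = 700, by = 5) seq(from, to, by = by)
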