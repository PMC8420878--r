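#' Monte-Carlo photon transport in a layered slab
#'
#' Weighted-photon random walk with Henyey-Greenstein scattering, Fresnel
#' handling at all interfaces and Russian roulette: an independent reference
#' for the adding-doubling solver (same geometry and detection convention:
#' collimated normal incidence, entry specular excluded). Standard errors
#' are estimated from batch-to-batch variation.
#'
#' @param layers list of layers, each a list with `mua`, `mus`, `g`,
#'   `thickness_cm`, `n`.
#' @param n_outside outside refractive index (default 1).
#' @param n_photons number of photon packets.
#' @param seed RNG seed (own generator, independent of R's RNG state).
#' @param n_batches batches for the standard-error estimate.
#' @return A list with `R`, `T`, `A`, their standard errors, `r_specular`
#'   and `n_photons`.
#' @export
mc_slab <- function(layers, n_outside = 1, n_photons = 1e5, seed = 1,
                    n_batches = 10) {
  cpp_mc_slab(
    vapply(layers, `[[`, numeric(1), "mua"),
    vapply(layers, `[[`, numeric(1), "mus"),
    vapply(layers, `[[`, numeric(1), "g"),
    vapply(layers, `[[`, numeric(1), "n"),
    vapply(layers, `[[`, numeric(1), "thickness_cm"),
    n_outside, as.integer(n_photons), as.integer(seed),
    as.integer(n_batches)
  )
}
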