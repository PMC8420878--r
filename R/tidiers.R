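#' Tidy a fitted spectrum
#'
#' @param x a `fit_result` from [fit_spectrum()].
#' @param ... unused.
#' @return A tibble with one row per parameter: `param`, `estimate`,
#'   `at_bound`.
#' @export
tidy.fit_result <- function(x, ...) {
  tibble::tibble(param = names(x$params), estimate = unname(x$params),
                 at_bound = unname(x$at_bound))
}

#' @rdname tidy.fit_result
#' @return `glance()`: a one-row tibble with `r_squared`, `converged`,
#'   `n_iter`, `residual_ss`.
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, converged = x$converged,
                 n_iter = x$n_iter, residual_ss = x$residual_ss)
}

#' Tidy a parameter map
#'
#' @param x a `parameter_map` from [fit_cube()].
#' @param ... unused.
#' @return The per-pixel tibble, one row per fitted pixel.
#' @export
tidy.parameter_map <- function(x, ...) x$pixels

#' @rdname tidy.parameter_map
#' @return `glance()`: one-row summary (pixel counts, convergence rate,
#'   median R^2, per-parameter means).
#' @export
glance.parameter_map <- function(x, ...) {
  out <- tibble::tibble(
    model = x$model,
    n_pixels = nrow(x$pixels),
    n_converged = sum(x$pixels$converged, na.rm = TRUE),
    median_r_squared = stats::median(x$pixels$r_squared, na.rm = TRUE))
  for (p in x$par_names) {
    out[[paste0("mean_", p)]] <- mean(x$pixels[[p]][x$pixels$valid],
                                      na.rm = TRUE)
  }
  out
}

#' Tidy an RT result
#'
#' @param x an `rt_result` from [ad_rt()].
#' @param ... unused.
#' @return One-row tibble with `r_total`, `t_total`, `a_total`,
#'   `r_specular`.
#' @export
tidy.rt_result <- function(x, ...) {
  tibble::tibble(r_total = x$r_total, t_total = x$t_total,
                 a_total = x$a_total, r_specular = x$r_specular)
}
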