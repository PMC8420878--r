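#' Plot a parameter map
#'
#' Heat map of one fitted parameter over the pixel grid.
#'
#' @param object a `parameter_map`.
#' @param param parameter to plot (default: first).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.parameter_map <- function(object, param = NULL, ...) {
  if (is.null(param)) param <- object$par_names[1]
  df <- object$pixels
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data[[param]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "column", y = "row", fill = param,
                  title = sprintf("%s map (%s)", param,
                                  if (length(object$corrections))
                                    paste(object$corrections, collapse = "+")
                                  else "uncorrected")) +
    ggplot2::theme_minimal()
}

#' Plot a single band of a reflectance cube
#'
#' @param object a [reflectance_cube()].
#' @param lambda_nm band to show (nearest match; default: middle band).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.reflectance_cube <- function(object, lambda_nm = NULL, ...) {
  if (is.null(lambda_nm)) lambda_nm <- stats::median(object$wavelengths)
  l <- which.min(abs(object$wavelengths - lambda_nm))
  band <- object$values[, , l]
  band[!object$valid] <- NA
  df <- tidyr::expand_grid(i = seq_len(nrow(band)), j = seq_len(ncol(band)))
  df$reflectance <- band[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$reflectance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "column", y = "row",
                  title = sprintf("reflectance at %.0f nm",
                                  object$wavelengths[l])) +
    ggplot2::theme_minimal()
}

#' Plot a radial profile
#'
#' @param profile tibble from [radial_average()].
#' @param truth optional horizontal reference (true value).
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(profile, truth = NULL) {
  p <- ggplot2::ggplot(profile[is.finite(profile$mean), ],
                       ggplot2::aes(x = .data$radius_mm, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (mm)", y = "extracted value") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_hline(yintercept = truth, linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
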