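#' Fit configuration
#'
#' Settings of the per-pixel spectral inversion: parameter bounds (taken from
#' the forward model unless overridden), the wavelength grid, the iteration
#' cap of the Levenberg-Marquardt optimizer, multi-start settings and the
#' seed, and the spatial/spectral binning applied before fitting.
#'
#' @param max_iterations LM iteration cap (default 200).
#' @param lambda_nm fitting grid (default [default_grid()]: 430-700 nm, 5 nm).
#' @param n_starts random initializations for [multistart_init()] (default
#'   1000).
#' @param n_polish how many of the best random starts get an LM polish during
#'   multi-start screening (default 10).
#' @param seed integer seed for all randomness in the fit.
#' @param batch_size spectra fitted per progress batch (default 500).
#' @param bin_factors `c(spatial, spectral)` binning applied by [fit_cube()]
#'   (default `c(8, 6)`, the instrument-scale reduction; synthetic desk-scale
#'   scenes typically use `c(1, 1)`).
#' @param lower,upper optional bound overrides (named as the model parameters).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(max_iterations = 200, lambda_nm = default_grid(),
                       n_starts = 1000, n_polish = 10, seed = 1,
                       batch_size = 500, bin_factors = c(8, 6),
                       lower = NULL, upper = NULL) {
  stopifnot(max_iterations >= 1, n_starts >= 1, batch_size >= 1)
  structure(list(max_iterations = max_iterations, lambda_nm = lambda_nm,
                 n_starts = n_starts, n_polish = n_polish, seed = seed,
                 batch_size = batch_size, bin_factors = bin_factors,
                 lower = lower, upper = upper),
            class = "fit_config")
}

model_bounds <- function(model, cfg) {
  lower <- model$lower; upper <- model$upper
  names(lower) <- names(upper) <- model$par_names
  if (!is.null(cfg$lower)) lower[names(cfg$lower)] <- cfg$lower
  if (!is.null(cfg$upper)) upper[names(cfg$upper)] <- cfg$upper
  stopifnot(all(lower < upper))
  list(lower = lower, upper = upper)
}

#' Fit a single reflectance spectrum
#'
#' Bounded Levenberg-Marquardt least squares via `minpack.lm::nls.lm` with
#' its native box constraints, minimizing the sum of squared reflectance
#' residuals over the grid. `r_squared` is computed against the
#' mean-spectrum null model. Fits whose residuals turn non-finite are marked
#' failed rather than raising. Parameters landing on a bound are flagged
#' (`at_bound`), which signals an inadequate fit, as when spectra are biased
#' beyond the model's reach.
#'
#' @param measured numeric reflectance vector on `model$lambda_nm`, or a
#'   tibble with `wavelength_nm` and `reflectance` (resampled linearly onto
#'   the model grid).
#' @param model a [forward_model()].
#' @param cfg a [fit_config()].
#' @param init named (or positional) initial parameter vector; defaults to
#'   mid-bounds.
#' @return A `fit_result`: list with `params` (named vector), `r_squared`,
#'   `converged`, `n_iter`, `at_bound` (logical per parameter), `residual_ss`.
#' @export
fit_spectrum <- function(measured, model, cfg = fit_config(), init = NULL) {
  stopifnot(inherits(model, "forward_model"))
  if (is.data.frame(measured)) {
    measured <- stats::approx(measured$wavelength_nm, measured$reflectance,
                              xout = model$lambda_nm, rule = 2)$y
  }
  stopifnot(length(measured) == length(model$lambda_nm))
  b <- model_bounds(model, cfg)
  lo <- b$lower; hi <- b$upper
  if (is.null(init)) init <- (lo + hi) / 2
  init <- pmin(pmax(unname(init), lo), hi)
  resid_fn <- function(p) {
    r <- tryCatch(model$forward(p) - measured,
                  error = function(e) rep(NA_real_, length(measured)))
    if (any(!is.finite(r))) rep(1e6, length(measured)) else r
  }
  # epsfcn widens the finite-difference step: the forward model is smooth but
  # carries ~1e-10 numerical roughness, which at the default machine-epsilon
  # step corrupts the Jacobian enough to stall LM in ill-conditioned valleys
  ctl <- minpack.lm::nls.lm.control(maxiter = cfg$max_iterations,
                                    maxfev = 100 * (length(lo) + 1) * 4,
                                    epsfcn = 1e-8)
  run_lm <- function(p0) {
    tryCatch(minpack.lm::nls.lm(par = p0, lower = unname(lo),
                                upper = unname(hi), fn = resid_fn,
                                control = ctl),
             error = function(e) NULL)
  }
  fit <- run_lm(init)
  # restart while the deviance still improves (resets the trust region)
  for (rs in 1:2) {
    if (is.null(fit) || any(!is.finite(fit$par))) break
    fit2 <- run_lm(fit$par)
    if (is.null(fit2) || fit2$deviance >= fit$deviance - 1e-14) break
    fit2$niter <- fit2$niter + fit$niter
    fit <- fit2
  }
  if (is.null(fit) || any(!is.finite(fit$par))) {
    return(structure(list(params = setNames(rep(NA_real_, length(lo)),
                                            model$par_names),
                          r_squared = NA_real_, converged = FALSE,
                          n_iter = 0L, at_bound = rep(NA, length(lo)),
                          residual_ss = NA_real_),
                     class = "fit_result"))
  }
  p <- fit$par
  names(p) <- model$par_names
  res <- model$forward(p) - measured
  ss_res <- sum(res^2)
  ss_tot <- sum((measured - mean(measured))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  tol_b <- 1e-3 * (hi - lo)
  structure(list(params = p, r_squared = r2,
                 converged = fit$info %in% 1:4 &&
                   all(is.finite(res)),
                 n_iter = fit$niter,
                 at_bound = (p - lo) < tol_b | (hi - p) < tol_b,
                 residual_ss = ss_res),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (isTRUE(x$converged)) "converged" else "NOT converged",
      sprintf("(R^2 = %.5f, %d iterations)\n", x$r_squared, x$n_iter))
  print(round(x$params, 5))
  if (any(x$at_bound, na.rm = TRUE)) {
    cat("  at bound:", paste(names(x$params)[which(x$at_bound)],
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Multi-start initialization from a characteristic region
#'
#' Draws `cfg$n_starts` parameter vectors uniformly within the bounds
#' (seeded), screens them by the goodness of fit of the forward spectrum
#' against the region-mean spectrum, runs a Levenberg-Marquardt polish on the
#' best `cfg$n_polish` candidates, and returns the parameters with the
#' highest resulting R-square. These serve as the shared initialization for
#' the whole-image fit, which converges much faster from a good global start
#' than from arbitrary values.
#'
#' @param region_spectrum mean reflectance of the characteristic region:
#'   numeric vector on the model grid or a tibble
#'   (`wavelength_nm`, `reflectance`).
#' @param model a [forward_model()].
#' @param cfg a [fit_config()].
#' @return A list with `init` (named parameter vector), `r_squared` and the
#'   screened `draws` tibble.
#' @export
multistart_init <- function(region_spectrum, model, cfg = fit_config()) {
  stopifnot(inherits(model, "forward_model"))
  if (is.data.frame(region_spectrum)) {
    region_spectrum <- stats::approx(region_spectrum$wavelength_nm,
                                     region_spectrum$reflectance,
                                     xout = model$lambda_nm, rule = 2)$y
  }
  b <- model_bounds(model, cfg)
  lo <- b$lower; hi <- b$upper
  np <- length(lo)
  draws <- withr::with_seed(cfg$seed, {
    matrix(runif(cfg$n_starts * np), ncol = np)
  })
  draws <- sweep(sweep(draws, 2, hi - lo, `*`), 2, lo, `+`)
  ss_tot <- sum((region_spectrum - mean(region_spectrum))^2)
  r2 <- apply(draws, 1, function(p) {
    r <- model$forward(p) - region_spectrum
    1 - sum(r^2) / ss_tot
  })
  ord <- order(r2, decreasing = TRUE)
  n_pol <- min(cfg$n_polish, cfg$n_starts)
  best <- NULL
  for (k in ord[seq_len(n_pol)]) {
    f <- fit_spectrum(region_spectrum, model, cfg, init = draws[k, ])
    if (is.null(best) || (is.finite(f$r_squared) &&
                          f$r_squared > best$r_squared)) best <- f
  }
  if (is.null(best) || !is.finite(best$r_squared)) {
    stop("all multi-start fits failed", call. = FALSE)
  }
  list(init = best$params, r_squared = best$r_squared,
       draws = tibble::tibble(r_squared = r2))
}

#' Fit every pixel of a reflectance cube
#'
#' Applies the configured spatial/spectral binning, resamples the spectral
#' axis onto the fitting grid, obtains a shared initialization from a
#' characteristic region via [multistart_init()], then runs the bounded
#' Levenberg-Marquardt fit per pixel (in batches; invalid pixels are
#' skipped, per-pixel failures masked). The cube's correction provenance is
#' recorded in the result.
#'
#' @param cube a [reflectance_cube()].
#' @param model a [forward_model()].
#' @param cfg a [fit_config()].
#' @param init_region integer list `list(rows =, cols =)` defining the
#'   characteristic region (default: central 10 x 10 block).
#' @param init optional explicit initial parameters (skips multi-start).
#' @param progress print per-batch progress (default FALSE).
#' @return A `parameter_map`: tidy per-pixel tibble `pixels`, map `shape`,
#'   `model` name, `corrections` provenance, `pixel_pitch`, and the shared
#'   `init` used.
#' @export
fit_cube <- function(cube, model, cfg = fit_config(), init_region = NULL,
                     init = NULL, progress = FALSE) {
  stopifnot(inherits(cube, "reflectance_cube"), inherits(model, "forward_model"))
  if (any(cfg$bin_factors > 1)) {
    cube <- bin_cube(cube, cfg$bin_factors[1],
                     max(1L, as.integer(cfg$bin_factors[2])))
  }
  d <- dim(cube$values)
  # spectral resampling onto the model grid
  need_resample <- !isTRUE(all.equal(cube$wavelengths, model$lambda_nm))
  if (need_resample) {
    rng <- range(cube$wavelengths)
    if (min(model$lambda_nm) < rng[1] - 1e-9 ||
        max(model$lambda_nm) > rng[2] + 1e-9) {
      stop("model grid extends beyond the cube's spectral range", call. = FALSE)
    }
  }
  get_spec <- function(i, j) {
    s <- cube$values[i, j, ]
    if (need_resample) {
      stats::approx(cube$wavelengths, s, xout = model$lambda_nm, rule = 2)$y
    } else s
  }
  if (is.null(init)) {
    if (is.null(init_region)) {
      half <- 5L
      ci <- max(1L, round(d[1] / 2) - half + 1L); cj <- max(1L, round(d[2] / 2) - half + 1L)
      init_region <- list(rows = ci:min(d[1], ci + 9L),
                          cols = cj:min(d[2], cj + 9L))
    }
    reg <- region_spectrum(cube, init_region$rows, init_region$cols)
    ms <- multistart_init(reg, model, cfg)
    init <- ms$init
  }
  idx <- which(cube$valid, arr.ind = TRUE)
  np <- length(model$par_names)
  nres <- nrow(idx)
  pmat <- matrix(NA_real_, nres, np)
  r2 <- rep(NA_real_, nres); conv <- rep(FALSE, nres)
  nit <- rep(NA_integer_, nres)
  atb <- matrix(NA, nres, np)
  # pixels are visited in column order; warm-starting each fit from the
  # previous pixel's solution exploits map smoothness and cuts iterations
  warm <- init
  for (s in seq_len(nres)) {
    f <- fit_spectrum(get_spec(idx[s, 1], idx[s, 2]), model, cfg, init = warm)
    pmat[s, ] <- f$params; r2[s] <- f$r_squared
    conv[s] <- f$converged; nit[s] <- f$n_iter; atb[s, ] <- f$at_bound
    if (f$converged && all(is.finite(f$params)) && !any(f$at_bound)) {
      warm <- f$params
    } else {
      warm <- init
    }
    if (progress && s %% cfg$batch_size == 0) {
      message(sprintf("fit_cube: %d / %d pixels", s, nres))
    }
  }
  px <- tibble::tibble(i = idx[, 1], j = idx[, 2])
  for (k in seq_len(np)) px[[model$par_names[k]]] <- pmat[, k]
  px$r_squared <- r2; px$converged <- conv; px$n_iter <- nit
  for (k in seq_len(np)) px[[paste0("at_bound_", model$par_names[k])]] <- atb[, k]
  px$valid <- conv & !is.na(r2)
  structure(list(pixels = px, shape = d[1:2], model = model$model,
                 par_names = model$par_names,
                 corrections = cube$corrections,
                 pixel_pitch = cube$pixel_pitch, init = init,
                 seed = cfg$seed),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %s model, %d x %d grid, %d fitted pixel(s)\n",
              x$model, x$shape[1], x$shape[2], nrow(x$pixels)))
  cat(sprintf("  corrections: %s; median R^2 = %.4f\n",
              if (length(x$corrections)) paste(x$corrections, collapse = ", ")
              else "none",
              stats::median(x$pixels$r_squared, na.rm = TRUE)))
  invisible(x)
}

#' Extract one parameter of a parameter map as a matrix
#'
#' @param map a `parameter_map`.
#' @param param parameter name (default: first).
#' @return Numeric matrix of the map's shape (NA where unfitted).
#' @export
map_matrix <- function(map, param = NULL) {
  stopifnot(inherits(map, "parameter_map"))
  if (is.null(param)) param <- map$par_names[1]
  m <- matrix(NA_real_, map$shape[1], map$shape[2])
  m[cbind(map$pixels$i, map$pixels$j)] <- map$pixels[[param]]
  m
}
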