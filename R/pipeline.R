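#' Pipeline configuration
#'
#' Assembles the end-to-end run configuration: the synthetic scene (or input
#' file paths), the fit settings, stage toggles and the validity threshold
#' of the cosine correction. Can be loaded from YAML via [read_pipeline_config()].
#'
#' @param scene a [scene_spec()] (or NULL when `cube_path`/`height_path` are
#'   given).
#' @param fit a [fit_config()].
#' @param model `"phantom"` or `"skin"` (default: the scene's model).
#' @param min_cos Lambert-correction validity threshold (default 0.1).
#' @param stages character subset of
#'   `c("simulate", "reconstruct", "calibrate", "correct", "fit", "metrics")`.
#' @param cube_path,height_path optional input files (read with
#'   [read_cube()] / [read_height()]) used when no scene is given.
#' @param seed master seed; overrides the scene and fit seeds.
#' @param out_dir optional output directory; when set, maps and the JSON
#'   report are written there.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_spec(), fit = fit_config(bin_factors = c(1, 1)),
                            model = NULL, min_cos = 0.1,
                            stages = c("simulate", "reconstruct", "calibrate",
                                       "correct", "fit", "metrics"),
                            cube_path = NULL, height_path = NULL,
                            seed = 1, out_dir = NULL) {
  if (!is.null(seed)) {
    if (!is.null(scene)) scene$seed <- seed
    fit$seed <- seed
  }
  if (is.null(model) && !is.null(scene)) model <- scene$model
  structure(list(scene = scene, fit = fit, model = model, min_cos = min_cos,
                 stages = stages, cube_path = cube_path,
                 height_path = height_path, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments; `scene` and `fit`
#' sub-maps are passed to [scene_spec()] and [fit_config()]. Skin materials
#' are given as `material: {type: skin, ...}` or
#' `material: {type: vot, phase: before}`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scene <- NULL
  if (!is.null(y$scene)) {
    sargs <- y$scene
    if (!is.null(sargs$material)) {
      m <- sargs$material
      sargs$material <- switch(
        m$type %||% "phantom",
        phantom = phantom_params(m$cabs_pct %||% 3.7, m$csc_pct %||% 1.6),
        skin = do.call(skin_params, m[setdiff(names(m), "type")]),
        vot = vot_phase_params(m$phase %||% "before"),
        stop("unknown material type", call. = FALSE))
    }
    scene <- do.call(scene_spec, sargs)
  }
  fit <- do.call(fit_config, y$fit %||% list(bin_factors = c(1, 1)))
  pipeline_config(scene = scene, fit = fit, model = y$model,
                  min_cos = y$min_cos %||% 0.1,
                  stages = y$stages %||% c("simulate", "reconstruct",
                                           "calibrate", "correct", "fit",
                                           "metrics"),
                  cube_path = y$cube_path, height_path = y$height_path,
                  seed = y$seed %||% 1, out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order: simulate (or ingest) the scene,
#' reconstruct the surface (harmonic hole filling, normals, incidence
#' cosines), fit the distance calibration, apply the height and Lambert
#' corrections, fit parameter maps for both the corrected and the
#' uncorrected branch, and compute radial profiles and the maximum valid
#' inclination angle per parameter and branch. Every stage logs its timing
#' and pixel-failure counts; a stage failure aborts with a machine-readable
#' error record.
#'
#' @param cfg a [pipeline_config()].
#' @param progress log stage progress via `message()` (default TRUE).
#' @return A `pipeline_report`: list with `report` (JSON-able summary:
#'   seed, config digest, per-parameter corrected/uncorrected maximum valid
#'   angles, map summaries, timings) and the intermediate objects (`scene`,
#'   `normals`, `corrected`, `maps`, `profiles`).
#' @export
run_pipeline <- function(cfg, progress = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t_all <- list()
  log_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    t_all[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    if (progress) message(sprintf("[%s] %.2fs", name, t_all[[name]]))
    out
  }
  stages <- cfg$stages

  # --- simulate / ingest ---
  scene <- NULL; cube <- NULL; height <- NULL
  if ("simulate" %in% stages && !is.null(cfg$scene)) {
    scene <- log_stage("simulate", generate_scene(cfg$scene))
    cube <- scene$cube
    height <- scene$height
  } else {
    if (is.null(cfg$cube_path)) {
      stop("no scene to simulate and no cube_path to ingest", call. = FALSE)
    }
    cube <- log_stage("ingest", read_cube(cfg$cube_path))
    if (!is.null(cfg$height_path)) height <- read_height(cfg$height_path)
  }

  # --- surface reconstruction ---
  normals <- NULL; ct <- NULL
  if ("reconstruct" %in% stages) {
    if (is.null(height)) stop("height map required for reconstruction",
                              call. = FALSE)
    rec <- log_stage("reconstruct", {
      hf <- laplace_fill(height)
      nf <- compute_normals(hf, pixel_pitch = cube$pixel_pitch)
      list(height = hf, normals = nf, cos_theta = cos_incidence(nf))
    })
    height <- rec$height; normals <- rec$normals; ct <- rec$cos_theta
  }

  # --- distance calibration ---
  cal <- NULL
  if ("calibrate" %in% stages && !is.null(cfg$scene)) {
    cal <- log_stage("calibrate", {
      ws <- simulate_white_stack(cfg$scene)
      fit_height_calibration(ws$intensities, ws$distances,
                             cfg$scene$working_distance)
    })
  }

  # --- corrections ---
  corrected <- NULL
  if ("correct" %in% stages) {
    if (is.null(height) || is.null(ct)) {
      stop("height map required for correction: enable the reconstruct stage or provide height_path",
           call. = FALSE)
    }
    corrected <- log_stage("correct", {
      x <- cube
      if (!is.null(cal)) x <- height_correct(x, height, cal)
      lambert_correct(x, ct, min_cos = cfg$min_cos,
                      require_height = !is.null(cal))
    })
  }

  # --- fits (paired branches) ---
  maps <- list()
  fm <- NULL
  if ("fit" %in% stages) {
    fm <- forward_model(cfg$model, cfg$fit$lambda_nm)
    maps$uncorrected <- log_stage("fit_uncorrected",
                                  fit_cube(cube, fm, cfg$fit))
    if (!is.null(corrected)) {
      maps$corrected <- log_stage("fit_corrected",
                                  fit_cube(corrected, fm, cfg$fit,
                                           init = maps$uncorrected$init))
    }
  }

  # --- metrics ---
  profiles <- list(); angles <- list()
  if ("metrics" %in% stages && length(maps)) {
    th <- if (!is.null(normals)) normals$theta else NULL
    met <- log_stage("metrics", {
      for (branch in names(maps)) {
        for (p in maps[[branch]]$par_names) {
          pr <- radial_average(maps[[branch]], p, theta = th)
          profiles[[paste(branch, p, sep = ".")]] <- pr
          angles[[paste(branch, p, sep = ".")]] <-
            max_valid_angle(pr)
        }
      }
      list(profiles = profiles, angles = angles)
    })
    profiles <- met$profiles; angles <- met$angles
  }

  report <- list(
    seed = cfg$seed,
    model = cfg$model,
    corrections = if (!is.null(corrected)) corrected$corrections else character(),
    config_hash = config_hash(cfg),
    max_valid_angle_deg = angles,
    map_summary = lapply(maps, function(m) as.list(glance(m))),
    timings_s = t_all
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (branch in names(maps)) {
      write_map(maps[[branch]], file.path(cfg$out_dir,
                                          paste0("map_", branch, ".csv")))
    }
  }
  structure(list(report = report, scene = scene, normals = normals,
                 corrected = corrected, maps = maps, profiles = profiles,
                 calibration = cal),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (length(x$report$max_valid_angle_deg)) {
    for (nm in names(x$report$max_valid_angle_deg)) {
      cat(sprintf("  max valid angle %-24s %5.1f deg\n", nm,
                  x$report$max_valid_angle_deg[[nm]]))
    }
  }
  invisible(x)
}

config_hash <- function(cfg) {
  # stable digest of the configuration without external dependencies
  s <- paste(utils::capture.output(utils::str(cfg, give.attr = FALSE)),
             collapse = "\n")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}
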