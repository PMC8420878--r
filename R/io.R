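#' Write a reflectance cube to disk
#'
#' Two dialects are supported. `"envi"` writes a classic header + flat binary
#' pair (`<path>.hdr`, `<path>.dat`) with float64 samples, which round-trips
#' bit-exactly; interleaves BSQ, BIL and BIP are supported. `"tiff"` writes a
#' multipage 32-bit float TIFF (one page per band) plus a JSON sidecar
#' (`<path>.json`) carrying the wavelength axis and grid metadata; values
#' round-trip within float32 precision. Pixel `(1, 1)` is the first scan
#' line's first sample in every dialect.
#'
#' @param cube a [reflectance_cube()].
#' @param path output path without extension.
#' @param dialect `"envi"` or `"tiff"`.
#' @param interleave ENVI interleave: `"bsq"`, `"bil"` or `"bip"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, dialect = c("envi", "tiff"),
                       interleave = "bsq") {
  stopifnot(inherits(cube, "reflectance_cube"))
  dialect <- match.arg(dialect)
  if (dialect == "envi") {
    write_envi(cube, path, interleave)
  } else {
    write_tiff_cube(cube, path)
  }
  invisible(path)
}

#' Read a reflectance cube from disk
#'
#' Counterpart of [write_cube()]. The dialect is guessed from the files
#' present unless given. A missing wavelength axis is an error: a cube
#' without its spectral axis cannot be paired with extinction tables.
#'
#' @param path path without extension, as passed to [write_cube()].
#' @param dialect `"envi"`, `"tiff"`, or `NULL` to guess.
#' @return A [reflectance_cube()].
#' @export
read_cube <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (file.exists(paste0(path, ".hdr"))) "envi" else "tiff"
  }
  if (dialect == "envi") read_envi(path) else read_tiff_cube(path)
}

write_envi <- function(cube, path, interleave = "bsq") {
  interleave <- match.arg(interleave, c("bsq", "bil", "bip"))
  d <- dim(cube$values)
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),   # sample, line, band
                 bil = c(2, 3, 1),   # sample, band, line
                 bip = c(3, 2, 1))   # band, sample, line
  vals <- aperm(cube$values, perm)
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, digits = 17), collapse = ", ")),
    sprintf("pixel pitch mm = { %s }",
            paste(format(cube$pixel_pitch, digits = 17), collapse = ", ")),
    sprintf("working distance mm = %s",
            format(cube$working_distance, digits = 17)),
    sprintf("corrections = { %s }", paste(cube$corrections, collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vals), con, size = 8, endian = "little")
  if (!all(cube$valid)) {
    con2 <- file(paste0(path, ".msk"), "wb")
    writeBin(as.integer(t(cube$valid)), con2, size = 1)
    close(con2)
  }
  invisible(path)
}

parse_envi_header <- function(lines) {
  out <- list()
  # merge { ... } groups that span lines before key = value parsing
  merged <- character(0)
  buf <- ""
  open <- FALSE
  for (ln in lines) {
    if (!open) buf <- ln else buf <- paste(buf, ln)
    open <- grepl("\\{", buf) && !grepl("\\}", buf)
    if (!open) { merged <- c(merged, buf); buf <- "" }
  }
  for (ln in merged) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub("[{}]", "", val)
    out[[key]] <- trimws(val)
  }
  out
}

read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path,
                                   call. = FALSE)
  lines <- readLines(hdr_path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ENVI") {
    stop("malformed ENVI header (missing magic line): ", hdr_path, call. = FALSE)
  }
  h <- parse_envi_header(lines)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("ENVI header missing field(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(h[["wavelength"]])) {
    stop("ENVI header has no wavelength list; a spectral axis is required",
         call. = FALSE)
  }
  ns <- as.integer(h[["samples"]]); nl <- as.integer(h[["lines"]])
  nb <- as.integer(h[["bands"]])
  dtype <- as.integer(h[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype, call. = FALSE))
  interleave <- tolower(h[["interleave"]])
  endian <- if (identical(h[["byte order"]], "1")) "big" else "little"
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = ns * nl * nb, size = size,
                  endian = endian)
  if (length(vals) != ns * nl * nb) {
    stop("ENVI binary shorter than header promises (axis-order mismatch?)",
         call. = FALSE)
  }
  arr <- switch(interleave,
                bsq = aperm(array(vals, dim = c(ns, nl, nb)), c(2, 1, 3)),
                bil = aperm(array(vals, dim = c(ns, nb, nl)), c(3, 1, 2)),
                bip = aperm(array(vals, dim = c(nb, ns, nl)), c(3, 2, 1)),
                stop("unsupported interleave: ", interleave, call. = FALSE))
  wl <- as.numeric(strsplit(h[["wavelength"]], ",")[[1]])
  pitch <- if (!is.null(h[["pixel pitch mm"]])) {
    as.numeric(strsplit(h[["pixel pitch mm"]], ",")[[1]])
  } else c(1, 1)
  wd <- if (!is.null(h[["working distance mm"]])) {
    as.numeric(h[["working distance mm"]])
  } else 300
  corr <- if (!is.null(h[["corrections"]]) && nzchar(h[["corrections"]])) {
    trimws(strsplit(h[["corrections"]], ",")[[1]])
  } else character()
  valid <- NULL
  msk_path <- paste0(path, ".msk")
  if (file.exists(msk_path)) {
    con2 <- file(msk_path, "rb")
    m <- readBin(con2, "integer", n = ns * nl, size = 1)
    close(con2)
    valid <- t(matrix(as.logical(m), ns, nl))
  }
  reflectance_cube(arr, wl, pitch, wd, valid = valid, corrections = corr)
}

# r-tiff stores samples in [0, 1]; arbitrary-range data are written with an
# affine scale recorded in the JSON sidecar
tiff_scale <- function(x) {
  rng <- range(x[is.finite(x)])
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
  list(offset = rng[1], scale = rng[2] - rng[1])
}

write_tiff_cube <- function(cube, path) {
  sc <- tiff_scale(cube$values)
  pages <- lapply(seq_len(dim(cube$values)[3L]), function(l) {
    v <- (cube$values[, , l] - sc$offset) / sc$scale
    v[!is.finite(v)] <- 0
    v
  })
  suppressWarnings(
    tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32,
                    reduce = FALSE)
  )
  meta <- list(wavelengths_nm = cube$wavelengths,
               pixel_pitch_mm = cube$pixel_pitch,
               working_distance_mm = cube$working_distance,
               corrections = cube$corrections,
               offset = sc$offset, scale = sc$scale,
               invalid = which(!cube$valid))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

read_tiff_cube <- function(path) {
  tif <- paste0(path, ".tif")
  js <- paste0(path, ".json")
  if (!file.exists(tif)) stop("TIFF not found: ", tif, call. = FALSE)
  if (!file.exists(js)) {
    stop("wavelength sidecar missing (", js, "); a spectral axis is required",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(tif, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  arr <- arr * meta$scale + meta$offset
  valid <- matrix(TRUE, dim(arr)[1], dim(arr)[2])
  if (length(meta$invalid)) valid[meta$invalid] <- FALSE
  reflectance_cube(arr, meta$wavelengths_nm, meta$pixel_pitch_mm,
                   meta$working_distance_mm, valid = valid,
                   corrections = as.character(unlist(meta$corrections)))
}

#' Write / read a height map as 32-bit float TIFF
#'
#' Heights are stored scaled to the unit interval (the TIFF writer's sample
#' range) with the affine scale and the invalid-point indices recorded in a
#' JSON sidecar `<path>.json`.
#'
#' @param h a [height_map()].
#' @param path file path (`.tif` appended if absent).
#' @return `path`, invisibly.
#' @export
write_height <- function(h, path) {
  stopifnot(inherits(h, "height_map"))
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  sc <- tiff_scale(h$z[h$valid])
  z <- (h$z - sc$offset) / sc$scale
  z[!h$valid] <- 0
  suppressWarnings(tiff::writeTIFF(z, path, bits.per.sample = 32,
                                   reduce = FALSE))
  jsonlite::write_json(list(offset = sc$offset, scale = sc$scale,
                            invalid = which(!h$valid)),
                       sub("\\.tif$", ".json", path), digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_height
#' @export
read_height <- function(path) {
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  z <- tiff::readTIFF(path, as.is = FALSE)
  js <- sub("\\.tif$", ".json", path)
  if (file.exists(js)) {
    meta <- jsonlite::read_json(js, simplifyVector = TRUE)
    z <- z * meta$scale + meta$offset
    if (length(meta$invalid)) z[meta$invalid] <- NA_real_
  } else {
    z[!is.finite(z)] <- NA_real_
  }
  height_map(z)
}

#' Write a parameter map to CSV
#'
#' Serializes the tidy per-pixel table of a fitted [parameter_map] (see
#' [fit_cube()]) to CSV, one row per pixel with its fitted parameters,
#' goodness of fit and validity.
#'
#' @param map a `parameter_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "parameter_map"))
  utils::write.csv(tibble::as_tibble(map$pixels), path, row.names = FALSE)
  invisible(path)
}
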