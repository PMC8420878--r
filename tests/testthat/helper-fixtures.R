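# Shared fixtures. Forward models are expensive to set up (Mie library and
# quadrature caches), so they are built once per test run.

shared_env <- new.env(parent = emptyenv())

get_phantom_model <- function() {
  if (is.null(shared_env$phantom)) shared_env$phantom <- forward_model("phantom")
  shared_env$phantom
}

get_skin_model <- function() {
  if (is.null(shared_env$skin)) shared_env$skin <- forward_model("skin")
  shared_env$skin
}

# small reflectance cube with a linear-in-lambda spectrum per pixel
make_test_cube <- function(nr = 4, nc = 5, wavelengths = seq(500, 520, 10),
                           value = 0.5) {
  vals <- array(value, c(nr, nc, length(wavelengths)))
  reflectance_cube(vals, wavelengths, pixel_pitch = c(0.5, 0.5),
                   working_distance = 300)
}

# small hemisphere scene spec with manageable runtime
small_hemisphere <- function(cabs = 3.7, csc = 1.6, npix = 21,
                             artifacts = list(), noise = list(), ...) {
  scene_spec(geometry = list(type = "hemisphere", radius_mm = 15,
                             npix = npix, pitch_mm = 30 / (npix - 1)),
             material = phantom_params(cabs, csc),
             artifacts = artifacts, noise = noise, ...)
}
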