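Package: hsicurve
Title: Curvature and Height Correction of Hyperspectral Reflectance Images
    with Adding-Doubling Parameter Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for correcting pushbroom hyperspectral reflectance images of
    curved samples using co-registered 3D surface data (Lambert cosine and
    camera-distance corrections), and for extracting tissue and phantom optical
    parameters from the corrected spectra. Includes laser-line triangulation
    height reconstruction with harmonic (Laplace) hole filling, surface normal
    and inclination-angle fields, a conical-flux adding-doubling radiative
    transfer solver for one- and two-layer slabs with mismatched boundaries,
    Lorenz-Mie scattering for polydisperse microsphere suspensions, chromophore
    models for a silicone phantom and a two-layer skin model, per-pixel bounded
    Levenberg-Marquardt inversion with multi-start initialization, radial map
    metrics, and a synthetic scene generator that emulates the imaging
    geometry so the whole pipeline can be exercised without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lhs
Config/testthat/edition: 3
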