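# hsicurve

Curvature and height correction of pushbroom hyperspectral reflectance
images, with adding–doubling extraction of tissue and phantom optical
parameters.

## The problem

Reflectance imaging of curved samples — hemispherical tissue phantoms,
fingers, any non-flat tissue — suffers two multiplicative artifacts that
corrupt every spectrum long before a tissue model sees it:

* **Lambert shading**: a surface element inclined by `θ` against the
  illumination receives irradiance reduced by `cos θ`, so the apparent
  reflectance is `I = I_true · cos θ`;
* **distance falloff**: the signal depends on the camera-to-surface
  distance `d = working_distance − z` through the illumination geometry.

When a co-registered 3-D surface is available (laser-line triangulation
profilometry, `ΔZ = L / (tan β + tan(α − arctan(ΔY/f)))`), both artifacts
can be inverted:

```
I_corr(λ) = I(λ) · ε(λ) / cos θ ,   ε(λ) = P(working_distance) / P(d)
```

with `P` a per-band quadratic calibration of white-standard intensity
versus distance, and `cos θ = n · l` from the reconstructed surface
normals. `hsicurve` implements this correction chain and everything needed
to quantify its effect on *extracted parameters*:

* surface reconstruction: triangulation, harmonic (Laplace) filling of
  laser-shadow holes, normal and inclination-angle fields;
* a conical-flux (M = 20) adding–doubling radiative-transfer solver for 1-
  and 2-layer slabs with refractive-index-mismatched boundaries, validated
  against an independent Monte-Carlo photon oracle;
* Lorenz–Mie scattering of polydisperse microsphere suspensions;
* a one-layer silicone-phantom model (`μa = C_AB μ_AB + C_abs μ_abs/0.13246`,
  `μs = C_sc μ_s,cal`) and a two-layer skin model (melanin epidermis over a
  blood/cytochrome dermis, `μs' = a (λ/500)^-1.27`, g = 0.82);
* per-pixel bounded Levenberg–Marquardt inversion with seeded 1000-draw
  multi-start initialization, and radial map metrics (the maximum
  inclination angle at which extracted maps stay within 5 % of the central
  value);
* a synthetic scene generator that stands in for the instrument, so the
  whole pipeline runs and is testable at desk scale.

The bundled extinction tables and sphere distribution are synthetic
stand-ins (files named `*_synthetic.csv`); see the methods vignette
(`vignettes/curvature-correction-methods.Rmd`) for what they do and do not
represent.

## Worked example

Simulate a hemispherical phantom scene with both artifacts, correct it,
fit both branches and compare their valid-angle ranges:

```r
library(hsicurve)

cfg <- pipeline_config(
  scene = scene_spec(
    geometry = list(type = "hemisphere", radius_mm = 15, npix = 17,
                    pitch_mm = 30 / 16),
    material = phantom_params(cabs_pct = 3.7, csc_pct = 1.6)),
  fit  = fit_config(bin_factors = c(1, 1), n_starts = 150, n_polish = 5),
  seed = 23)

rep <- run_pipeline(cfg, progress = FALSE)
rep
#> <pipeline_report>
#>   max valid angle uncorrected.cabs_pct       8.8 deg
#>   max valid angle uncorrected.csc_pct        8.8 deg
#>   max valid angle corrected.cabs_pct        42.5 deg
#>   max valid angle corrected.csc_pct         42.5 deg
```

The uncorrected maps are trustworthy only in the flat centre of the
hemisphere (inclination below ~9°); after the height and Lambert
corrections the same 5 %-accuracy criterion holds out to ~43° on this
scene. In the centre the corrected map recovers the true composition
(3.7 % absorber, 1.6 % scatterer) to a few tenths of a percent:

```r
glance(rep$maps$corrected)
tidy(rep$maps$corrected)            # per-pixel tibble
autoplot(rep$maps$corrected)        # ggplot heat map
```

Lower-level entry points: `normalize_reflectance()`, `bin_cube()`,
`triangulate_height()`, `laplace_fill()`, `compute_normals()`,
`height_correct()`, `lambert_correct()`, `build_slab()`, `ad_rt()`,
`forward_spectrum()`, `mc_slab()`, `mie_sphere()`,
`distribution_scattering()`, `fit_spectrum()`, `multistart_init()`,
`fit_cube()`, `radial_average()`, `max_valid_angle()`,
`generate_scene()`, `vot_phase_params()`. A thin command-line wrapper
with subcommands (`simulate`, `reconstruct`, `calibrate-height`,
`correct`, `fit`, `metrics`, `run`) is installed at
`system.file("cli", "hsicurve", package = "hsicurve")`.

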