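---
title: "Curvature and height correction of hyperspectral reflectance images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature and height correction of hyperspectral reflectance images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsicurve)
```

## The problem

A pushbroom hyperspectral camera records a datacube `I(i, j, lambda)` of
normalized reflectance. When the imaged object is curved, two instrumental
artifacts corrupt the cube long before any tissue model sees it:

* **Lambert shading.** A surface element inclined by `theta` against the
  illumination direction receives irradiance reduced by `cos(theta)`, so its
  apparent reflectance is `I = I_true * cos(theta)`.
* **Distance falloff.** The irradiance also depends on the camera-to-surface
  distance; a pixel sitting `z` millimetres above the reference plane is
  `working_distance - z` away from the camera and appears brighter or dimmer
  according to the illumination geometry.

Both artifacts are multiplicative and can be removed when the 3-D surface is
known. `hsicurve` implements the full chain: surface reconstruction from
laser-line triangulation, harmonic filling of laser-shadow holes, normal and
inclination-angle fields, the two corrections, a conical-flux adding-doubling
radiative-transfer solver, per-pixel inversion of phantom and skin optical
models, and the map metrics used to quantify how far up the inclination range
the corrected maps remain accurate. A synthetic scene generator stands in for
the instrument so that every stage can be exercised, end to end, without
hardware.

## Surface model

The profilometer converts a laser-line displacement `dy` on the detector into
a height difference

```
dz = L / ( tan(beta) + tan(alpha - atan(dy / f)) )
```

with baseline `L` (mm), incidence angle `alpha`, observation angle `beta` and
focal length `f`. `triangulate_height()` evaluates this per point and
invalidates geometrically impossible configurations (non-positive
denominator). The relation gives relative heights; anchoring an absolute
height is left to the caller, and the synthetic scenes generate `z` directly.

Laser shadowing leaves holes. `laplace_fill()` replaces missing points by the
discrete harmonic solution of the 5-point Laplacian with Dirichlet data from
the valid neighbours. We solve the sparse symmetric positive-definite system
with a direct sparse Cholesky factorization rather than an iterative
conjugate-gradient sweep: the holes are small, the direct solve is exact to
solver precision (residuals far below 1e-8 of the data range), and it removes
an iteration-tolerance knob. Filled values obey the discrete maximum
principle, which the tests check on random fields.

Normals come from central differences of the height field (one-sided at the
borders), optionally after a Gaussian pre-smooth whose sigma (in pixels) is
exposed because real profilometry is noisy; the default is no smoothing. The
inclination angle is measured against the illumination direction, by default
the vertical optical axis `(0, 0, 1)`, matching a system whose LED panels are
aligned around the camera axis.

## The corrections

`height_correct()` multiplies each pixel and band by
`eps(lambda) = P(working_distance) / P(d)`, where `P` is a per-band quadratic
fit of mean white-standard intensity versus distance
(`fit_height_calibration()`) and `d = working_distance - z`. Over the +/-20 mm
excursions of interest a quadratic tracks the inverse-square falloff to well
below one percent. The sign convention — camera distance decreases as `z`
increases — is used consistently by the corrections and the scene generator.

`lambert_correct()` then divides by `cos(theta)`. The order (height first,
then Lambert) is fixed, and the Lambert step refuses cubes that do not carry
the height-correction provenance flag unless explicitly overridden. Pixels
with `cos(theta)` below `min_cos` (default 0.1, about 84 degrees) are masked
instead of corrected: beyond that the `1/cos` factor amplifies noise without
bound and profilometry is unreliable anyway. Masked pixels are never altered.

On noiseless synthetic scenes the two corrections invert the generator's
artifact operator to better than 1e-10 relative error — a closure property the
acceptance suite checks — because both are exact algebraic inverses when the
surface and calibration are exact.

## Radiative transfer: adding-doubling with conical fluxes

Reflectance spectra are linked to optical properties by a one-dimensional
multi-stream (discrete-ordinates) slab solver. The radiance field is
discretized into `M = 20` conical fluxes whose cosines are Gauss-Radau nodes
including `mu = 1`, so collimated normal illumination maps exactly onto a
cone. For an index-mismatched slab the cosine interval is split at the
critical cosine, half the cones sampling the totally-internally-reflected
range, half the escaping range.

Scattering between cones uses the azimuthally averaged Henyey-Greenstein
redistribution, built from the Legendre addition theorem and symmetrically
renormalized so that a conservative layer conserves energy exactly under the
quadrature. Homogeneous layers are solved by two routes that agree to ~1e-8
and cross-check each other in the tests:

* **Doubling** from a thin starting layer (second-order initialization of the
  transfer generator, starting thickness 1e-5 in optical depth), the textbook
  construction; used for conservative layers.
* **Modal solution**: the two-point boundary-value problem decouples into the
  eigenmodes of `(A - B)(A + B)`; assembling the boundary conditions with
  exponentials scaled as `exp(-k tau)` keeps everything finite for arbitrarily
  thick layers and is exact in `tau`. This is the fast path used by the
  per-pixel fits (for a single layer the Fresnel boundary conditions are
  folded straight into the modal system).

Fresnel boundary operators (total internal reflection below the critical
cosine) and layer stacks are combined with the standard adding equations.
The collimated specular reflection at the top interface is excluded from the
reported diffuse reflectance, mimicking cross-polarized detection; it is
reported separately, and the bookkeeping `R + T + A + specular = 1` closes to
1e-6 or better. Slabs thicker than `tau = 1000` are treated as
non-transmitting.

The solver is validated against an independently implemented Monte-Carlo
photon random walk (weighted packets, Henyey-Greenstein sampling, Fresnel
handling at every interface, Russian roulette) over a Latin-hypercube of
absorption 0.1-1.1 1/cm and reduced scattering 8-40 1/cm — the property
ranges of the phantom set — with agreement within `max(0.003, 3 SE)`.

## Material models

**Phantom (one layer, 2 cm).** Absorption combines the clear-silicone medium
and the diluted pigment, `mua = (1 - Cabs) muAB + Cabs muabs / 0.13246`; the
constant 0.13246 rescales for the mismatch between the dilution used when the
pigment was characterized and the recipe's 1:2272 pre-dilution, and both are
stored in `phantom_recipe`, not hard-coded. Scattering comes from a Lorenz-Mie
library over the bundled sphere-size distribution:
`mus_i = 3 phi_i Qsca_i / (4 r_i)` per radius bin, summed per unit scatterer
volume fraction, with the scattering-weighted anisotropy. The refractive index
follows the one-term Sellmeier fit of the silicone.

**Skin (epidermis 100 um over dermis 1 cm).** Epidermal absorption is the
melanin power law `6.6e11 lambda^-3.33` times the melanin volume fraction
plus the 0.25 1/cm bloodless baseline; dermal absorption sums deoxy- and
oxyhemoglobin (volume fractions, whole-blood extinction), bilirubin and the
two cytochrome c oxidase redox states (millimolar), plus the same baseline.
Both layers share the reduced-scattering power law `a (lambda/500)^-b` with
`b = 1.27` fixed, anisotropy `g = 0.82`, and a Cauchy-type index dispersion.
The six free parameters and their bounds are in `skin_bounds()`; bilirubin is
carried by the model but fixed at 0 mM by default because it is not one of
the free parameters and no canonical value is available.

### The bundled synthetic tables

No measured extinction tables or sphere distributions ship with the package;
the bundled CSVs (all named `*_synthetic.csv`) are smooth band models that
carry the qualitative features of the real compilations: Soret and Q bands
and isosbestic crossings for hemoglobin, the 460 nm bilirubin band, a sharp
605 nm alpha band for reduced cytochrome c oxidase against a broad oxidized
spectrum, a spectrally near-neutral black pigment over a structured clear
medium, and a log-normal sphere-volume distribution on 1-16 um.

Two calibration choices were made once, before any acceptance run, and are
worth recording:

* The sphere library uses an effective homogeneous sphere index of 1.59.
  Plain fused silica in silicone has so little index contrast that no
  distribution on 1-16 um radii can reach the documented reduced-scattering
  band (8-40 1/cm at 1.6-7 % volume fraction); the real microspheres carry a
  ~1 um shell that dominates their scattering, and 1.59 is a shell-like
  effective value. The distribution scale was then set so the library spans
  that band. A coated-sphere mode ([mie_coated_sphere()], and `shell_um` /
  `n_shell` in `distribution_scattering()`) is available for users who have
  a shell index; no documented value exists, so the homogeneous-equivalent
  index is the default.
* The pigment is spectrally near-neutral while the medium carries the
  structure. Identifiability of `(Cabs, Csc)` requires the absorber and
  medium shapes to differ; putting the structure into the pigment instead
  turns out to flip the direction of the shading bias (uniform dimming gets
  absorbed by the scatterer term), contradicting the documented behaviour
  that uncorrected inclined areas read high absorber and low scatterer. The
  neutral-pigment design satisfies both constraints.

Consequences for interpretation: passing tests demonstrate the pipeline's
internal consistency — closure of the corrections, solver validity against an
independent oracle, identifiability and artifact response under the synthetic
library — not agreement with any particular measured phantom. Real data would
swap in measured tables via the `tables =` arguments without code changes.

## Inversion

`fit_spectrum()` minimizes the unweighted sum of squared reflectance
residuals over the 430-700 nm grid at 5 nm steps (the upper limit is
configurable; visible-range polarizers and chromophore contrast motivate the
default). The optimizer is Levenberg-Marquardt with box constraints
(`minpack.lm`), capped at 200 iterations. Three numerical choices matter:

* **Native bounds instead of a logistic transform.** A logistic
  reparameterization was tried first and abandoned: it reshapes the already
  long, curved `(Cabs, Csc)` valley badly enough that LM stalls on a
  trust-region collapse far from the optimum, while the native bounded
  implementation converges. Bound landings remain exactly detectable and are
  flagged per parameter (`at_bound`), signalling inadequate fits, e.g. where
  artifacts push spectra outside the model's reach.
* **Finite-difference step.** The forward model is smooth but carries ~1e-10
  numerical roughness; at the default machine-epsilon step this corrupts the
  numerical Jacobian enough to stall LM in ill-conditioned valleys. A
  relative step of about 1e-4 (`epsfcn = 1e-8`) restores exact convergence.
* **Restarts.** The fit is restarted (at most twice) while the deviance still
  improves; restarting resets the trust region cheaply.

`R^2` is computed against the mean-spectrum null model; how the original
processing normalized its goodness of fit is not documented, and this choice
is recorded here as ours.

`multistart_init()` implements the global initialization: parameters are
drawn uniformly within bounds (1000 draws by default, seeded), screened by
the R^2 of their forward spectra against the region-mean spectrum of a
characteristic 10 x 10 block (scene centre by default, where the surface is
flat), and the best few candidates (default 10) receive an LM polish; the
highest-R^2 result initializes the whole-map fit. Screening before polishing
keeps the cost at one forward evaluation per draw instead of one full fit per
draw while preserving the best-of-many-starts behaviour the procedure exists
for: the phantom objective has genuine local minima that a single mid-bounds
start falls into.

`fit_cube()` bins (by default 8 x spatially and 6 x spectrally — the
instrument-scale reduction; the desk-scale synthetic scenes use 1 x 1),
resamples spectra onto the model grid, and fits pixels in scan order,
warm-starting each fit from the previous pixel's solution (falling back to
the shared initialization after failures or bound landings). On smooth maps
this cuts per-pixel iteration counts by an order of magnitude. Identical
seeds and inputs give bit-identical maps.

## Map metrics

`radial_average()` bins a fitted map into concentric annuli (means, standard
deviations and the annulus-mean inclination angle), and `max_valid_angle()`
returns the largest inclination angle up to which every annulus stays within
5 % (configurable) of the central value, the central value being the mean of
the flat central region. On synthetic hemispheres the corrected branch
sustains several times the uncorrected branch's angle, and low-absorption
scenes lose validity earlier than high-absorption ones when uncorrected —
the orderings the acceptance suite asserts.

## Scene generator

`generate_scene()` composes exactly the forward process the corrections
assume: truth parameters -> forward reflectance spectrum -> multiplication by
`cos(theta)` (analytic geometry normals) and by the quadratic distance
falloff -> optional additive interreflection term -> multiplicative Gaussian
noise; alongside, a height map with Gaussian noise (the 0.05 mm vertical
resolution of the profilometer is the natural noise scale) and optional
punched laser-shadow holes. Geometries: a 15 mm hemisphere on a base plane
(the phantom mould), a tilted plane, and a finger-like cylinder for the
occlusion-test scenes, whose phase presets (`vot_phase_params()`) encode the
expected hemodynamics: deoxyhemoglobin up during occlusion, oxyhemoglobin
overshooting after release, melanin constant throughout.

The interreflection term is deliberately crude — a constant additive ambient
fraction in steep regions — because its only job is to let tests confirm that
the cosine correction does *not* remove additive light. The generator makes
no attempt at physically based rendering, speckle or polarization.

Default problem sizes (41 x 41 scenes in the examples, 15-21 pixel grids in
the test suite, 2e5 photons per Monte-Carlo point in the acceptance script,
8-point designs in the test blocks) were chosen so the full suite and the
acceptance script each complete in minutes on a single core while leaving the
statistical checks well-resolved; they are package defaults, not physical
constants, and every one is configurable.

## Known limitations

* The corrections assume purely multiplicative artifacts: additive
  interreflection in concave scenes (finger folds) survives them by design.
* Validity degrades above ~60-70 degrees of inclination even with exact
  surfaces; with noisy profilometry the usable range shrinks further, and
  pixels beyond `min_cos` are masked, not rescued.
* The layer solver is unpolarized and one-dimensional (no lateral transport);
  fluence/depth profiles are out of scope.
* The bundled tables are synthetic stand-ins (see above); quantitative
  agreement with measured phantoms requires measured tables.
* Blood concentrations are reported as volume fractions; conversion to molar
  units is left to the user.
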