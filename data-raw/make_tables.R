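# Generates the bundled synthetic optical-property tables under inst/extdata.
# All tables are synthetic constructions: smooth band models with the known
# qualitative features of the real compilations (peak positions, isosbestic
# structure, magnitudes), chosen once so the phantom recipe's concentration
# ranges map onto absorption coefficients of ~0.1-1.1 1/cm and reduced
# scattering of ~8-40 1/cm. Run from the package root:
#   Rscript data-raw/make_tables.R

lambda <- seq(400, 750, by = 2)
gauss <- function(c, s) exp(-(lambda - c)^2 / (2 * s^2))

# --- chromophores ----------------------------------------------------------
# whole-blood convention: mua (1/cm) at 100 % blood volume fraction
hbo2 <- 2800 * gauss(415, 16) + 280 * gauss(542, 12) + 310 * gauss(577, 10) +
  25 * gauss(500, 45) + 1.5
hb <- 3000 * gauss(430, 16) + 290 * gauss(555, 20) + 60 * gauss(480, 35) +
  25 * exp(-(lambda - 600) / 80) * (lambda > 600) +
  25 * (lambda <= 600) * exp(-(600 - lambda) / 200) + 3
# bilirubin, 1/cm per mM (molar band near 460 nm)
bilirubin <- 127 * gauss(460, 34) + 0.05
# cytochrome c oxidase, 1/cm per mM: reduced has the sharp 605-nm alpha band
# and a 445-nm Soret; oxidized is broader and weaker in the visible
cyt_red <- 60 * gauss(445, 18) + 12 * gauss(520, 30) + 46 * gauss(605, 12) + 0.3
cyt_ox <- 40 * gauss(425, 25) + 8 * gauss(540, 50) + 6 * gauss(660, 60) + 0.3

chrom <- rbind(
  data.frame(chromophore = "hb", wavelength_nm = lambda, value = hb,
             units = "1/cm per unit blood volume fraction"),
  data.frame(chromophore = "hbo2", wavelength_nm = lambda, value = hbo2,
             units = "1/cm per unit blood volume fraction"),
  data.frame(chromophore = "bilirubin", wavelength_nm = lambda,
             value = bilirubin, units = "1/cm per mM"),
  data.frame(chromophore = "cyt_red", wavelength_nm = lambda, value = cyt_red,
             units = "1/cm per mM"),
  data.frame(chromophore = "cyt_ox", wavelength_nm = lambda, value = cyt_ox,
             units = "1/cm per mM")
)
chrom$value <- signif(chrom$value, 6)
write.csv(chrom, "inst/extdata/chromophores_synthetic.csv", row.names = FALSE)

# --- phantom absorption ----------------------------------------------------
# clear polymerized silicone: weak with a steep blue rise and a mild
# mid-visible band; its spectral shape must differ from the pigment's so
# absorber and medium contributions are separable in the inverse problem
medium <- 0.07 + 0.2 * exp(-(lambda - 400) / 45) + 0.06 * gauss(560, 40)
# diluted black pigment at measurement mass fraction 5.83e-5: spectrally
# near-neutral with a slight negative slope (carbon-black-like)
pigment <- 0.38 - 2e-4 * (lambda - 430)
phant <- data.frame(wavelength_nm = lambda,
                    medium = signif(medium, 6),
                    pigment = signif(pigment, 6))
write.csv(phant, "inst/extdata/phantom_absorption_synthetic.csv",
          row.names = FALSE)

# --- microsphere size distribution -----------------------------------------
# log-normal volume-fraction distribution on 1-16 um; total sphere volume
# fraction 0.85 of the raw scatterer powder
radius <- seq(1, 16, by = 0.75)
w <- exp(-(log(radius) - log(1.6))^2 / (2 * 0.5^2))
w <- 0.85 * w / sum(w)
dist <- data.frame(radius_um = radius, volume_fraction = signif(w, 6))
write.csv(dist, "inst/extdata/sphere_distribution_synthetic.csv",
          row.names = FALSE)

cat("tables written to inst/extdata\n")
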