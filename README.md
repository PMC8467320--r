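# ppdxdeg

Quantitative assessment of the hydrolytic degradation of polydioxanone
(PPDX) medical stent fiber.

PPDX is a semi-crystalline biodegradable polyester used in esophageal and
airway stents. In simulated body fluid it degrades by ester-bond
hydrolysis, preferentially in the amorphous phase; tracking that process
matters both clinically (when does the stent lose integrity?) and for
manufacturing control. `ppdxdeg` implements three complementary
measurements and the statistical workflow that connects them, plus a
synthetic-data generator with known ground truth so the whole pipeline is
testable without instrument data.

## What it computes

**Raman shoulder metric.** The ester carbonyl band at 1732 cm⁻¹ carries a
high-wavenumber shoulder attributed to C=O vibrations in the amorphous
phase. After baseline removal (asymmetric least squares, or piecewise
linear through anchors), the degradation metric is

> A = ∫₁₇₃₆¹⁷⁴⁹ I(ν̃) / I₁₇₃₂ dν̃  [cm⁻¹]

i.e. the area under the shoulder between 1736 and 1749 cm⁻¹ after
normalizing the spectrum to the 1732 cm⁻¹ peak height. The metric shrinks
monotonically as the amorphous phase is hydrolyzed. Spectra are processed
in the acquisition layout — an 8 × 8 grid of spots per specimen — and
summarized per degradation period.

**Crack morphometry.** On binary masks derived from SEM images, every
crack is measured with six descriptors: area, perimeter, Feret (maximum
caliper) diameter and angle, aspect ratio of the moment-fitted ellipse
(AR = major/minor), circularity (4π·area/perimeter²) and solidity
(area/convex area). Labeling, boundary tracing, convex hull, rotating
calipers and the moment ellipse are implemented from scratch and verified
against brute-force oracles and analytic shapes.

**DSC crystallinity.** The melting endotherm of a heating scan is
integrated over an explicit window above a linear baseline and converted
to percent crystallinity via X = 100·ΔH/ΔH_ref, with ΔH_ref the melting
enthalpy of fully crystalline PPDX (packaged default 141 J g⁻¹, a
literature convention).

**Statistics.** Per-period samples are screened with the D'Agostino K²
omnibus normality test (mean ± SD display when normal, median with
quartiles otherwise) and consecutive periods are compared with paired
Wilcoxon signed-rank tests (exact enumeration for small n, tie- and
continuity-corrected normal approximation otherwise) under Bonferroni
familywise-error control: five periods give four comparisons and a
per-test α of 0.05/4 = 0.0125.

## Worked example

Generate a synthetic non-degraded specimen (8 × 8 spectra, 5% per-band
amplitude variation, 2% noise, calibrated so the noiseless reference
metric is 9.83 cm⁻¹), run baseline correction and the shoulder metric, and
summarize:

```r
library(ppdxdeg)

prof <- default_profiles()          # calibrated periods 0/4/8/16/24 weeks
grid <- generate_degradation_series(prof[1], seed = 42)[["0"]]
metrics <- grid_shoulder_metrics(grid, method = "asls")
summarize_sample(metrics$normalized_area)
#> mean±SD: 9.785 ± 0.476 (n = 64)
```

The grid mean (9.785 cm⁻¹, SEM 0.059) recovers the calibrated reference
value of 9.83 cm⁻¹ within two standard errors; the `mean±SD` display
means the 64 spot values passed the normality screen.

Crystallinity from a synthetic thermogram generated at 47.6%:

```r
tg <- generate_thermogram(47.6, dH_ref = 141, noise_sd = 0.002, seed = 7)
crystallinity(integrate_endotherm(tg, 81, 129), 141)
#> <crystallinity: 47.5 % (delta_H 66.9 J/g, ref 141 J/g)>
```

Morphometry of a 24-week-style crack population (200 elliptical cracks,
lognormal major axis with median 5.21 µm, orientations N(89°, 19.1°)):

```r
spec <- crack_population_spec(200, dist_lognormal(5.21, 0.6),
                              dist_fixed(5), dist_normal(89, 19.1))
recs <- measure_all_cracks(generate_crack_mask(spec, seed = 11)$mask)
summarize_cracks(recs)$summary[, c("descriptor", "mean", "sd", "median")]
#>       descriptor   mean       sd median
#> 1 feret_diameter  6.188  4.02282  5.112
#> 2    feret_angle 88.249 19.51994 86.282
#> 3           area  8.493 14.02208  4.060
#> 4   aspect_ratio  4.980  0.04647  4.989
#> 5    circularity  0.449  0.00671  0.448
#> 6       solidity  0.933  0.03160  0.940
```

The measured Feret-angle mean (88.2°) recovers the drawn orientation
center of 89°, and the median Feret diameter tracks the drawn median
length. `run_synthetic(run_config(...))` chains all of the above over a
full degradation series and renders the three report tables plus the
comparison table; `run_user_data()` runs the same measurements on files
on disk. A command-line wrapper lives at `inst/cli/ppdx-degrade.R`.

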