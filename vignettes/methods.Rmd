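---
title: "Methods: quantifying polydioxanone stent degradation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying polydioxanone stent degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdxdeg)
```

# The measurement problem

Polydioxanone (PPDX) stents degrade in the body by hydrolysis of their
ester bonds. The chemistry attacks the amorphous phase first, which shows
up in three independent observables: the amorphous-phase carbonyl
contribution next to the 1732 cm⁻¹ Raman band shrinks, the crystalline
fraction measured by DSC rises until the amorphous reservoir is spent,
and surface cracks nucleate and grow roughly perpendicular to the fiber
axis. `ppdxdeg` packages all three measurements behind a common pipeline,
with a synthetic-data generator that fabricates raw data — spectra, crack
masks, thermograms — from known ground truth so that every stage can be
tested quantitatively.

# The Raman shoulder metric

A baseline-corrected spectrum is normalized to the height of the
1732 cm⁻¹ ester carbonyl peak and the normalized intensity is integrated
(trapezoid rule) over 1736–1749 cm⁻¹. The result has units of cm⁻¹ and is
bounded by the 13 cm⁻¹ window width whenever the normalized intensity
stays below 1. Because the metric is a ratio, it is invariant to overall
intensity scaling — laser power, focus, collection efficiency — which is
what makes it usable across specimens.

Two conventions needed fixing where the procedure is underdetermined:

* **Peak height.** The 1732 cm⁻¹ height is the maximum within ±5 cm⁻¹
  (argmax), with ties broken to the lowest wavenumber; a fixed-position
  mode reads the intensity at exactly 1732 cm⁻¹ instead. Argmax is the
  default because grid steps of 1 cm⁻¹ rarely place a sample exactly on
  the band maximum. On noisy spectra an argmax estimator is biased high
  by roughly the noise SD, which in turn biases the metric low by a
  fraction of a percent; this is accepted as part of the method rather
  than silently smoothing the data.
* **Window edges.** The integral limits 1736 and 1749 are enforced
  exactly by linear interpolation at the window edges even when they fall
  between grid points.

## Baseline correction

The baseline estimator is asymmetric least squares (AsLS): iteratively
reweighted Whittaker smoothing, where points above the running baseline
receive weight `p` and points below `1 − p`. Defaults were chosen by a
fixed criterion — the correction must distort the shoulder metric of a
clean, baseline-free spectrum by less than 0.5% while exactly removing
linear and gently curved backgrounds:

* `lambda = 1e6` (smoothness). A softer penalty (1e5) lets the baseline
  ride up under the ~60 cm⁻¹-wide carbonyl cluster and clips the metric
  by ~1.7%; a stiffer one (1e7) can no longer follow curved
  fluorescence-like backgrounds.
* `p = 0.001` (asymmetry). Larger values shave peak area.
* `smooth_halfwin = 7` points. The baseline is estimated on a
  15-point moving-average copy of the trace. This matters because the
  curvature penalty does not penalize a constant shift, so with a
  strongly asymmetric `p` the baseline of a *noisy* trace settles on the
  lower noise envelope (≈1.4 SD low), which would inflate everything
  above it. Estimating on the smoothed copy suppresses that shift; the
  spectrum that is quantified is never smoothed.

A piecewise-linear anchor baseline (`linear_anchors`) is provided as the
transparent fallback: anchor levels are medians around user-chosen
wavenumbers, linearly interpolated. On spectra with a known flat
background it reproduces the clean metric within 2%.

# Crack morphometry

Input is a binary mask plus an isotropic pixel size. All angles are
reported in the mathematical frame (y up, counterclockwise from the
horizontal, wrapped to [0, 180)), so populations perpendicular to the
fiber axis center near 90°.

* **Labeling**: flood fill, 8-connectivity by default (thin diagonal
  cracks stay connected), deterministic row-major first-seen label order.
* **Boundary**: the outer contour polygon on the pixel-corner lattice;
  holes are ignored.
* **Convex hull**: Andrew's monotone chain; degenerate collinear input
  yields a two-point segment hull.
* **Feret diameter/angle**: the maximum caliper over hull vertices via
  rotating calipers (exhaustive for tiny hulls), which the test-suite
  checks against the exhaustive pairwise maximum on 1000 random hulls.
* **Fitted ellipse**: second-order central moments (with the 1/12
  square-pixel term), orientation from the principal axes, and axes
  rescaled so the ellipse area equals the pixel area. The rescaling
  convention leaves the aspect ratio untouched and matches the behavior
  of the interactive tools practitioners use for such measurements.
* **Perimeter**: the minimal 8-connected chain of boundary pixel centers
  (staircase pairs collapsed to diagonal steps), weighted per
  Vossepoel–Smeulders — 0.980 per orthogonal step, 1.406 per diagonal,
  −0.091 per corner — plus a π·pixel half-pixel outset term accounting
  for the half-pixel inset of center paths around convex shapes. On a
  digitized disk of radius 40 px the estimate is within 0.2% of 2πr, and
  descriptor anisotropy under rotation of a digitized 3:1 ellipse stays
  below 1%. A plain unit/√2 chain was rejected: it overestimates curved
  perimeters by ~5%, pushing disk circularity to ~0.90. For components
  spanning only a few pixels the estimator is biased (a single pixel has
  no chain); circularity is clipped at 1 and such records should be
  filtered by size.
* **Solidity** uses the hull of the corner polygon, so it is exactly 1
  for axis-aligned rectangles and slightly below 1 for digitized curved
  or rotated shapes.

Components touching the image border are measured but flagged
(`touches_border`), leaving the filtering decision to the analyst.

# DSC crystallinity

`integrate_endotherm` subtracts a linear baseline drawn between the
heat-flow levels at the window limits and integrates the excess over
temperature, dividing by the scan rate in °C s⁻¹ so W g⁻¹ × °C closes to
J g⁻¹. The anchor level at each limit is the mean over a ±1 °C
neighborhood (`edge_halfwin`), not a single sample: a single noisy anchor
propagates its error across the whole window and alone would cost nearly
±1 percentage point of crystallinity. Crystallinity is 100·ΔH/ΔH_ref;
`dH_ref` defaults to 141 J g⁻¹, documented as a literature convention for
PPDX rather than a measured constant — absolute crystallinity values
scale inversely with it, trends do not. The endotherm sign convention is
explicit (`endo_up`); a strongly negative net area raises an error
instead of silently flipping sign. Integration windows are explicit in
the tested path (105 ± 24 °C, i.e. peak ± 3 FWHM for the synthetic
endotherm); automatic window detection was deliberately left out as
fragile on noisy baselines.

# Statistics

Normality is screened with the D'Agostino K² omnibus test (z-transformed
skewness by the Johnson SU mapping plus z-transformed kurtosis by the
Anscombe–Glynn mapping, against χ²₂), implemented from the standard
formulas and verified against an independent implementation to 10
decimals; it requires n ≥ 8. Summaries display mean ± SD when the screen
passes and median (Q1, Q3) otherwise, with type-7 quantiles.

Consecutive degradation periods are compared with the paired Wilcoxon
signed-rank test. Pairing across physically distinct specimens is an
interpretation: the package pairs by grid position index (spot i against
spot i), with an unpaired rank-sum fallback (`paired = FALSE`). Zero
differences are dropped (Wilcoxon's rule; Pratt's variant available), at
least 6 non-zero pairs are required, ties get midranks. The exact
two-sided p comes from a dynamic-programming enumeration of the
signed-rank distribution (n ≤ 20 by default); beyond that a normal
approximation with implicit tie correction (Var = Σrᵢ²/4) and continuity
correction is used, which agrees with the exact p to within 0.01 at
n = 20. Five periods give four consecutive-period comparisons —
chosen over all-pairs because consecutive differences are the scientific
question (did degradation progress between visits?) — and Bonferroni
control at familywise 0.05 yields a per-test α of 0.0125.

# The synthetic-data generator

The generator fabricates the study conditions, not arbitrary data:

* **Spectra.** Pseudo-Voigt bands (`shape_mix`·Lorentzian +
  (1−`shape_mix`)·Gaussian, shared center/FWHM). The PPDX bands sit at
  870 (strongest, internal standard), 1048, 1451 and 1732 cm⁻¹; the five
  dye bands at 483/1242/1403/1610/1638 cm⁻¹ scale with `dye_level`; the
  amorphous shoulder is one broad Gaussian at 1742 cm⁻¹ (FWHM 14 cm⁻¹),
  the midpoint of the integration window, with height `shoulder_level`
  times the 1732 band height. Absolute band heights (870 at 1000 counts,
  carbonyl at 400, dye bands 40–60) are package conventions — the source
  measurements publish no amplitude ratios — and the default background
  is a gentle linear ramp typical of low-fluorescence 785 nm polymer
  spectra. The default grid is 200–1800 cm⁻¹ at 1 cm⁻¹.
* **Calibration.** `calibrate_shoulder_level` solves (uniroot, tol 1e-8)
  for the shoulder scale at which the noiseless reference spectrum yields
  a requested metric value; `default_profiles()` pins the five periods to
  the published series 9.83, 9.24, 7.97, 6.65, 6.30 cm⁻¹, together with
  crystallinity 47.6/54.8/60.9/69.7/59.2% and a monotone dye decline
  (1 → 0.15). Because calibration runs through the same `shoulder_area`
  code used for measurement, the reference metric hits its target by
  construction, and recovery tests probe only the noise, variability and
  baseline-removal path.
* **Grid variability.** Each band's height gets an independent per-spot
  lognormal factor (mean 1, CV 5%). Independence per band matters: the
  metric is scale-invariant, so one common factor per spot would produce
  zero metric spread and make the downstream statistics vacuous. Additive
  Gaussian noise defaults to 2% of the carbonyl height.
* **Cracks.** Filled ellipses rasterized into an 84 × 63 µm field
  (default 0.066 µm/px). The whole population (lengths, aspects, angles)
  is drawn first and placement rejects on position only — redrawing sizes
  after a rejection would bias the placed population small. Larger cracks
  are placed first; non-merged cracks may not even touch diagonally, so
  ground truth is one component per crack. With `merge_prob`, cracks
  chain collinearly end-to-end with a small tip overlap (tangent tips
  rasterize with a gap).
* **Thermograms.** A Gaussian endotherm at 105 °C (FWHM 8 °C) on a
  −30…150 °C scan at 5 °C min⁻¹, amplitude chosen so the integrated
  specific enthalpy equals `crystallinity_pct`/100 × `dH_ref`.

What the generator does *not* emulate — and hence what passing recovery
tests do not demonstrate — includes instrument spectral response and
cosmic-ray spikes, Poisson shot noise (noise is additive Gaussian),
real SEM contrast and the manual segmentation step (masks are already
binary), baseline drift correlated across a grid, and any coupling
between the three modalities beyond their shared period labels.

# Problem sizes and numerical conventions

The shipped tests and the acceptance script run at the study's own
scales: 8 × 8 spectra per period over five periods, 200 cracks per
field, three thermogram replicates; a full synthetic run takes seconds
to a few tens of seconds. Determinism is part of the contract: all
generators take explicit seeds, the pipeline config names one seed per
stage, and identical configs produce byte-identical report CSVs. CSV
outputs use "." decimals and header rows; the "±" rendering appears only
in the human-readable display column, never in machine-read fields.
AsLS raises an error carrying the iteration count if reweighting has not
converged within `max_iter`; a single-replicate crystallinity SD is
reported as missing, never as 0.

# Known limitations

* Absolute per-period values (shoulder areas, crystallinity, crack
  sizes) are *recovery targets built into the generator*, not
  reproductions from deposited instrument data — none exist. The
  package demonstrates that its measurement path recovers known truth
  under realistic noise, which is a statement about the method, not
  about any particular specimen.
* The median of a 200-draw lognormal sample carries ~5% sampling error
  on its own; crack-size recovery at that population size is dominated
  by sampling, not by measurement error (<1%).
* Perimeter (hence circularity) is unreliable for components spanning
  fewer than ~10 pixels.
* The paired comparison across physically distinct stents inherits
  whatever pairing the grid index encodes; with no true spot-to-spot
  correspondence it is effectively a conservative location test, and
  the unpaired fallback is provided.
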