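Package: ppdxdeg
Title: Quantitative Assessment of Polydioxanone Stent Fiber Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the hydrolytic degradation of polydioxanone
    (PPDX) medical stent fiber from three complementary modalities: a Raman
    peak-shoulder metric (the area under the shoulder of the 1732 cm-1 ester
    carbonyl peak, normalized to the peak height), crack morphometry on binary
    SEM-derived masks (Feret diameter and angle, area, aspect ratio,
    circularity, solidity), and DSC melting-enthalpy crystallinity. Includes
    asymmetric-least-squares baseline correction, a nonparametric statistical
    workflow (D'Agostino omnibus normality screening, paired Wilcoxon
    signed-rank comparisons across degradation periods with Bonferroni
    control), and a synthetic-data generator (pseudo-Voigt spectrum mixtures,
    rasterized crack populations, Gaussian melting endotherms) with known
    ground truth so that every pipeline stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
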