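Package: ciliaquant
Title: Quantification of Subciliary Protein Localization in Super-Resolution Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measurement pipeline for subciliary protein localization in
    photoreceptor connecting cilia and epithelial primary cilia. Provides a
    synthetic cilium image generator (ground-truth emitter sets, SIM-like
    renders, STORM-like blinking frame stacks), a single-molecule
    localization stage (candidate detection, elliptical Gaussian PSF
    fitting, acceptance filtering, frame linking, Gaussian rendering), the
    straighten / row-average-profile / fractional-threshold measurement
    pipeline (lengths, radii, edge offsets, asymmetry, TEM shortest
    diameters, layer intensity fractions), and the group statistics the
    field applies to such measurement tables (Student t, one-way ANOVA
    with Tukey or Dunnett post hoc correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
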