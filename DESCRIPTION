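Package: somatomap
Title: Phase-Encoded Somatotopic Mapping and Map Statistics on Cortical Surface Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phase-encoded (traveling-wave) fMRI somatotopy on
    triangulated cortical surface patches. Provides a synthetic-data module
    (flat and spherical meshes, ground-truth finger maps, periodic BOLD time
    series, Fisher-distributed direction samples, synthetic clinical tables),
    first-level Fourier phase mapping with an F-ratio test against noise
    frequencies and surface-based Monte-Carlo cluster correction, map measures
    (ROI surface area, spherical centroids, geodesic distances), directional
    group comparison via the Watson F test with an F-based Bayes factor,
    functional map geometry (complex smoothing, circularly-subtracted plane-fit
    phase gradients, circular variance, Harrison-Kanji two-factor circular
    ANOVA, circular-linear correlation), and group statistics (side pooling,
    pooled-variance t tests, JZS Bayes factors, 2x2 mixed ANOVA, Shapiro-Wilk
    plus log-transform pipeline, Fisher-z comparison of correlations,
    Benjamini-Hochberg critical values, and a pressure-pain severity score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr
Config/testthat/edition: 3
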