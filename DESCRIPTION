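Package: lymphomorph
Title: Lymphatic Microvessel Morphometry and Risk Analysis for Tumor Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies lymphatic microvascularization in stained histology
    images of tumor tissue cores. Segments ring-shaped stained vessels
    (closing open-outline walls by chord joining), measures per-vessel
    density, size and shape descriptors on the internal lumen, classifies
    vessels into caliber classes (5-15, 15-20, 20-50 and 50-200 micrometre
    longest axis), and aggregates per-sample quantity metrics. Provides the
    accompanying inferential layer: median dichotomization, Mann-Whitney
    group contrasts, binary logistic risk modeling with backward
    elimination and odds-product risk scoring, Rice-rule histograms with
    excess-kurtosis heterogeneity statistics, and Kaplan-Meier / Cox
    survival analysis with backward Wald elimination. A seeded synthetic
    tissue-microarray generator produces images with ground truth and a
    synthetic patient cohort so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    survival,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
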