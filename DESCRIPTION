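Package: ccmorph
Title: Pointwise Corpus Callosum Thickness Morphometry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates pointwise corpus callosum thickness profiles from traced
    midsagittal boundary contours (equidistant arc-length resampling, spatially
    averaged midline, callosal distance values at 100 positions) and compares
    diagnostic groups with a mass-univariate ANCOVA using group-centered
    clinical covariates and Benjamini-Hochberg false discovery rate control.
    Includes a synthetic cohort generator with group-specific regional thinning
    for validation, summary-statistics ANOVA, noncentral-F power calculations,
    and a reproducible study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
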