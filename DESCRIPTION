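Package: fertcurves
Title: Parametric Models for Age-Specific Fertility Schedules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits parametric fertility curves to age-specific fertility
    rate (ASFR) schedules by bounded nonlinear least squares. Implements
    the flexible generalized skew-logistic density (a logistic base pdf
    skewed by a logistic cdf with a cubic odd argument) alongside the
    classical alternatives it competes with: the Hadwiger function and
    its two-component mixture, the Peristera-Kostaki normal-mixture
    curve, the Schmertmann quadratic spline, and the flexible
    generalized skew-normal. Provides multistart box-constrained
    fitting, residual and mode diagnostics, side-by-side model
    comparison by residual sum of squares, readers and writers for CSV
    and Human Fertility Database ASFR layouts, a synthetic-schedule
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
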