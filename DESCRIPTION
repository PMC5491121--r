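Package: proxyrel
Title: Reliability of Temperature Signals in Biological and Physical
    Indicator Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how reliably annual indicator time series (plant
    phenology dates, lake and sea ice dates and extents, tree-ring width,
    density and stable-isotope chronologies) encode seasonal and annual
    mean temperatures.  Linear and least-angle-regression (LARS) models are
    evaluated with repeated five-fold cross-validation; model complexity is
    chosen by a second, inner level of repeated cross-validation; the
    reliability statistic is one minus the ratio of unexplained to total
    temperature variance in the validation data, with percentile bootstrap
    confidence intervals.  Includes tools to build tree-ring chronologies
    from Tucson/RWL measurement files (spline detrending, AR(1)
    prewhitening, Tukey biweight robust means) and a synthetic-data
    generator with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
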