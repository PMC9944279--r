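Package: aggsink
Title: Biophysics of Sinking Phytoplankton Aggregates and Fungal Infection Censuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sinking-aggregate experiments with
    phytoplankton cultures and their fungal microparasites: image-based
    particle detection (background flattening, channel arithmetic, global
    thresholding, connected-component measurement), geometric size-class
    number and volume spectra, Stokes-law settling physics (excess density,
    porosity, drag coefficient, Reynolds number, fractal dimension from
    size~velocity power-law fits), oxygen-drawdown respirometry converted to
    carbon-specific remineralization length scales, and infection-census
    statistics (prevalence, aggregate enrichment, per-aggregate bacterial
    loads, a Shapiro/F-test driven pairwise-test decision tree, and Gaussian
    error propagation). A seeded synthetic-data module generates every input
    the pipeline consumes so that all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
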