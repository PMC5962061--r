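Package: stripdsm
Title: Density Surface Modelling for Strip-Transect Aerial Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage density surface modelling for strip-transect count
    surveys: flight paths and georeferenced sighting records are cut into
    equal-effort segments, per-segment counts are modelled as penalized
    regression splines of environmental covariates with a Tweedie response,
    log link and effort-area offset, smoothing parameters are selected by a
    Laplace-approximate REML criterion, residual autocorrelation along
    transects is diagnosed and corrected with an AR(1) working correlation,
    and abundance with delta-method coefficients of variation is predicted
    over an exclusion-filtered grid. A synthetic-data module simulates
    landscapes, seasonal populations and surveys with the statistical
    structure the analysis assumes, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mgcv,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
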