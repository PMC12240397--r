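Package: linnean
Title: Discovery Curves, Asymptotic Richness and Completeness of a National Flora
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how many species of a regional flora remain undescribed
    from the publication years of scientific names. Builds decade-binned species
    discovery curves from name-level nomenclatural records (with majority-rule
    basionym resolution and family remapping), fits four asymptotic growth
    models (Gompertz 3P/4P, Logistic 3P, Weibull) by nonlinear least squares,
    combines them by Akaike-weight model averaging with unconditional standard
    errors, fits a taxonomic-effort discovery model linking description rates
    to taxonomist numbers, computes per-stratum completeness indices, regresses
    description counts on human population density and taxonomist counts, and
    maps grid-based discovery priorities with protected-area and
    Indigenous-land overlap statistics. Includes a synthetic-data generator
    with known ground truth for end-to-end validation.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
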