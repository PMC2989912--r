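Package: fruitscape
Title: Spatially and Temporally Explicit Fruit-Availability Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits spatial point-process, aerial-detectability and crossed
    random-effects phenology models to tree census and fruit-trap data, then
    composes them into stochastic simulations of daily fruit production per
    tree across a study landscape. Includes kernel intensity estimation with
    bandwidth selection, inhomogeneous Poisson fitting by Berman-Turner
    quadrature, simulation-envelope goodness-of-fit diagnostics,
    rank-transformation sampling of stem diameters, Poisson and Gaussian
    crossed-random-effects phenology models with parametric-bootstrap
    variance-component tests, and a synthetic-data generator emulating the
    full observation process.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lme4,
    sp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
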