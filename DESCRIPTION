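Package: airburden
Title: Health Damage Assessment for Point-Source Air Pollution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating the public-health burden of
    a point emission source such as a waste incinerator: builds per-pollutant
    emission scenarios from throughput and emission factors, disperses them
    with a steady-state Gaussian plume model (Briggs plume rise,
    Pasquill-Gifford stability classes, urban and rural dispersion
    coefficients), assigns annual-average concentration increments to census
    tracts, converts them to attributable cases with log-linear
    concentration-response functions, monetizes damages with value-of-a-
    statistical-life and cost-of-illness valuations in constant dollars, and
    screens social-vulnerability covariates for disparities with Gaussian
    generalized linear models. Includes a synthetic study-area generator
    (tract polygons, populations, meteorology, vulnerability covariates with
    planted effects) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
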