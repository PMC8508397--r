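Package: erythemal
Title: Erythemal UV Exposure Analysis for Ground Station Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing minute-resolution erythemal ultraviolet index
    (UVI) measurements from ground stations alongside satellite and model
    estimates. Provides a low-precision solar ephemeris, an analytic clear-sky
    UVI model driven by total ozone column and altitude, two clear-sky
    detection methods (a cloud-fraction threshold filter and a bell-shape
    deviation filter) with automatic threshold selection, standard erythemal
    dose (SED) accumulation against Fitzpatrick phototype thresholds, WHO
    exposure category statistics, ground-versus-estimate colocation statistics,
    monthly and diurnal climatologies, and a seeded synthetic data generator
    that emulates a tropical island station with a diurnal cloud cycle, cloud
    attenuation and broken-cloud enhancement, and satellite overpass sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
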