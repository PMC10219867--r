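Package: edcast
Title: Prospective Early-Warning Forecasting of Emergency Department Crowding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hourly Holt-Winters (ETS) forecasting of emergency department
    arrivals and occupancy, a rolling-origin prospective harness that issues
    24-hour-ahead point forecasts every hour and persists them to an
    append-only prediction store, a quartile-based operational definition of
    crowding built on daily peak occupancy, and a binary early-warning
    evaluation framework (performance per horizon, performance per origin,
    origin-by-horizon AUC matrices, bootstrap confidence intervals, and
    class-balanced downsampling). A mechanistic synthetic emergency
    department generator (nonhomogeneous Poisson arrivals feeding an
    infinite-server length-of-stay queue) reproduces the diurnal structure
    of real departments so the whole pipeline can be exercised end to end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    lubridate,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    optparse,
    jsonlite
Config/testthat/edition: 3
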