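Package: greycast
Title: Grey GM(1,1) Forecasting for Short Annual Resource Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the first-order one-variable grey model GM(1,1) to short,
    strictly positive annual time series, the setting typical of regional
    health-resource planning where only a handful of yearly counts are
    available.  Provides the accumulated generating operation (AGO) and its
    inverse, least-squares estimation of the development coefficient and grey
    input, multi-step forecasting via the time-response function,
    residual-based adequacy grading (posterior error ratio and small-error
    probability), per-thousand-population plan-gap indicators, and a seeded
    synthetic-series generator for parameter-recovery experiments.  Ships the
    2015-2022 Jilin Province health-resource series and the province's
    14th 5-Year-Plan 2025 targets as a worked example.  All user-facing
    functions take data frames and return tibbles; broom-style tidy(),
    glance() and augment() methods and ggplot2 autoplot() methods are
    provided for fitted models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
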