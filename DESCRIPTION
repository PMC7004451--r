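Package: heatpm
Title: Joint Effects of Fine Particulate Matter and Extreme Heat Events in
    Early Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the joint association of fine particulate
    matter (PM2.5) and extreme heat events (EHEs) during the cardiogenesis
    window of pregnancy in case-control studies of congenital heart defects.
    Builds gestational exposure windows (postconceptional weeks 3-8), links
    residences to the nearest PM2.5 monitor (within 50 km) and weather
    station, detects extreme heat events from seasonal Tmax percentile run
    rules, and estimates interaction on the multiplicative scale (product-term
    logistic regression with likelihood-ratio tests and stratum-specific odds
    ratios) and on the additive scale (relative excess risk due to
    interaction, RERI, with profile-likelihood and delta-method confidence
    intervals). Includes a synthetic-data module that emulates the structure
    of a population-based case-control study so the full pipeline can be
    exercised and calibrated without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    lubridate,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
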