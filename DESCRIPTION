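Package: kelpvol
Title: Kelp Canopy-Cover Volatility Under Warm-Season Marine Heatwaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying how kelp canopy-cover change responds to
    warm-season temperature extremes across a species' range. Computes
    day-of-year sea-surface-temperature climatologies and warm-season
    heatwave metrics (mean temperature, maximum and cumulative intensity,
    temperature tendency) from daily SST series, pairs consecutive canopy
    surveys into per-summer change observations, estimates per-population
    response slopes with site random intercepts, fits O'Neill thermal
    performance curves to net-photosynthesis data to derive Topt and CTmax,
    and reconstructs realised thermal ranges from gridded occurrence
    records. A seeded synthetic-data generator emulates the statistical
    structure of the daily SST, survey, physiology, and occurrence inputs
    so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
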