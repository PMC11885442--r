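Package: whalemigrate
Title: Satellite-Telemetry Track Processing and Breeding-Migration
    Phenology for Deep-Diving Whales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for Argos satellite-telemetry data from
    deep-diving whales tagged at high latitudes: plausibility filtering of
    Doppler locations (speed/distance/angle filter), regularization of
    irregular fixes with a continuous-time random-walk state-space model
    predicted on a 2-hour grid, movement metrics (speed, bearing, move
    persistence, time-spent-in-area on a 50 km equal-area grid), a
    migration-phenology detector that classifies migrants, delineates the
    northern foraging polygon, and dates departures, breeding-area arrivals
    and returns, and summaries of tag-transmitted binned dive records.
    Includes a synthetic-data generator that emulates multi-phase
    migratory movement, Argos sampling error and transmission gaps, and
    binned dive records, carrying ground truth so every stage of the
    pipeline can be validated without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    grDevices,
    tibble,
    tools,
    utils
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
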