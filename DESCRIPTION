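Package: pamtrackr
Title: Passive Acoustic 3D Tracking of Deep-Diving Whales from Paired
    Hydrophone Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for three-dimensional passive
    acoustic tracking of deep-diving echolocating whales using two seafloor
    small-aperture (tetrahedral, four-hydrophone) arrays. Provides a
    synthetic-scene generator (bathymetry, dive trajectories, click
    emission, propagation and detection), time-difference-of-arrival (TDOA)
    measurement and direction-of-arrival (DOA) inversion, two-ray cross-fix
    localization with jackknife confidence intervals, Kalman plus
    moving-average track smoothing, receiver self-calibration from ship
    noise, dive-behavior metrics (encounter segmentation, dive-phase
    classification, descent angle, swim speeds, altitude above the
    seafloor), a Monte Carlo model of the probability that a click is
    detected on both arrays, and group-behavior statistics (pairs distance,
    lane distance, closest-approach lags, single-linkage subgrouping, and
    track-density maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
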