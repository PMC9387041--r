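Package: actisleep
Title: Sleep/Wake Scoring and Validation for Waist-Worn Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores 2-minute waist-actigraphy epochs as sleep or wake with a
    five-epoch linear discriminant developed for school-aged children,
    collapses 30-second polysomnography hypnograms to the same epoch grid,
    computes run-length-based sleep parameters (sleep latency, wake after
    sleep onset, total sleep time, sleep efficiency) with an exhaustive
    run-length optimization search, and validates actigraphic scoring against
    polysomnography with epoch-by-epoch agreement, sensitivity, specificity,
    per-stage agreement and intraclass correlation.  Includes a
    discriminant-derivation stage (Fisher rule rescaled to a unit decision
    boundary), split-sample utilities, and a seeded Markov-chain simulator of
    paired hypnograms and activity-count series for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
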