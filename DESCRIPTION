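Package: wearagree
Title: Agreement and Equivalence Analysis for Wearable Device Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within-person validation of wrist-worn health monitors against
    clinical reference devices: paired device/reference time-series alignment
    and 10-second epoching, resting heart rate via the lowest sliding 5-minute
    median, error and coverage metrics, Bland-Altman limits of agreement,
    equivalence testing of ratios via paired log-ratio TOST with exact
    t-based sample-size calculation, and second-by-second activity-type
    confusion matrices. Includes a synthetic cohort simulator that emulates a
    laboratory validation protocol (rest plus short scripted activities) and
    free-living wear, so the full analysis pipeline is testable end to end
    without access to participant recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
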