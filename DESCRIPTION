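Package: crisistri
Title: Triangulated Identification of Regional Social-Media Users During
    Localized Disasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based pipeline for identifying the regional users of a
    social-media platform around a localized disaster, modelled on the
    2013 Hattiesburg EF-4 tornado. Normalizes JSON-lines tweet activity
    streams into flat tables, applies broad keyword/hashtag/profile/GPS
    extraction rules with a homonym purge, triangulates user regionality
    from three evidence channels (news-outlet mentions, biography terms,
    free-text location terms and ZIP codes) with inclusive/exclusive
    criterion accounting, validates assignments against region polygons
    by point-in-polygon GPS confirmation, computes survey sample sizes
    under confidence/margin-of-error standards with finite-population
    correction, and aggregates event-centered pre/post window summaries
    and hourly activity series. Includes a seeded synthetic corpus
    generator with ground-truth labels so every stage is testable
    without proprietary platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
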