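Package: foundorfly
Title: Flight Morphometrics and Reproduction-Dispersal Tradeoffs in Ant Queens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dispersal polymorphisms in queen-polymorphic
    ants. Computes standard flight-morphology indices (flight muscle ratio,
    wing loading, prolate-spheroid abdomen volume and drag reference area,
    aspect ratio, wing mass density) from dry morphometric measurements, runs
    normality-gated caste comparisons with Holm-Bonferroni familywise
    correction, fits upper-quartile quantile regressions of tethered-flight
    endurance on morphology with an exact point-pair solver and seeded
    bootstrap inference, and evaluates a found-or-fly tradeoff model that
    converts abdomen nutrient mass into maximum flight duration, flight range,
    potential colonization area, and first-generation worker production. A
    seeded synthetic-queen generator reproduces the statistical structure of
    tropical and red imported fire ant queen castes so the full pipeline is
    testable without specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
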