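Package: homereach
Title: Geographical Accessibility Analysis for Home Medical Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analyzing regional disparity in
    geographical accessibility to home medical care. Identifies provider
    facilities from medical claims records, simulates hypothetical patients
    on a population mesh proportionally to the population aged 75 years and
    over, computes closest-facility travel distance and time on a road
    network, and contrasts an actual scenario (observed providers only)
    against an ideal scenario (all hospitals and clinics) with
    per-municipality median/IQR travel costs and threshold-exceedance
    rates. Includes a synthetic-prefecture generator with ground-truth
    bookkeeping so every stage is testable without confidential claims
    data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    readr,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
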