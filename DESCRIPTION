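Package: recap3
Title: Three-Source Capture-Recapture Estimation of Registry Population Size
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links three overlapping administrative rosters into an
    incomplete 2^3 capture-history table by a deterministic key cascade,
    fits the eight hierarchical log-linear capture-recapture models by
    Poisson maximum likelihood, selects among them by deviance-based
    information criteria, and estimates the total (observed plus
    unobserved) population with log-normal confidence intervals,
    registration completeness, and per-1,000 population rates. Includes a
    synthetic-registry generator for end-to-end validation and a solver
    that back-solves unpublished capture-history cell counts from
    published closed-form estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
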