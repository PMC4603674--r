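Package: cogtrend
Title: Group-Stratified Cognitive Trend Projection and Demographic Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting population-level cognitive ability from
    group-level assessment trends. Converts raw assessment-scale summaries to
    a benchmark-standardized (IQ-like) metric, fits anchored per-group linear
    trends over configurable periods, projects group and population-weighted
    averages to a horizon year using time-varying demographic composition
    shares, decomposes the projected change into baseline-trend, minority
    catch-up, composition and interaction components via an exact four-term
    identity, and converts ability change into per-capita economic gain.
    Includes a seeded synthetic-data generator for parameter-recovery
    experiments and packaged fixtures of the published input tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    ggplot2,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
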