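Package: paleorange
Title: Stratigraphic Range Vetting and Abundance-Longevity Analysis for
    Microfossil Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether relative abundance predicts
    stratigraphic longevity in microfossil (e.g. polycystine radiolarian)
    occurrence time series. Reads age-dated sample-by-species count
    matrices, vets species ranges with gap-based error bars on first and
    last occurrences (edge, range-doubling and interval-overflow filters),
    computes per-species longevity and relative-abundance summaries and
    Good-Turing/Chao sample coverage, and runs the inferential battery:
    ordinary least-squares regressions of longevity on log abundance with
    residual diagnostics, one-way ANOVAs by taxonomic order and
    biogeographic category, linear mixed-effects models, and small-sample
    AICc model comparison. Includes seed-deterministic synthetic occurrence
    generators - a zero-sum Moran neutral-drift community simulator, a
    niche-structured generator with tunable abundance-longevity coupling,
    and Southern-Ocean / eastern-equatorial-Pacific shaped fixtures - so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmtest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
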