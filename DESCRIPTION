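Package: footprintr
Title: Metabolic Footprinting Analysis for Arrayed Nutrient-Transporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing arrayed RNAi screens that monitor amino-acid
    consumption and release in cell-culture medium (metabolic footprinting).
    Builds cell-number-adjusted consumption/release atlases from peak-area and
    cell-count tables, classifies and clusters them, and runs a sequential
    hit-selection cascade that separates genuine transporter hits from
    growth-only confounders using a serine-auxotroph versus serine-tolerant
    growth differential. Also provides natural-isotope-abundance correction for
    stable-isotope tracer data, per-cell nutrient flux quantification
    (standard curves, timed tracer consumption, 24-hour exchange fluxes,
    uptake-curve AUC), the accompanying statistical toolbox (one-sample t-tests
    on log ratios, Welch's t, one-way ANOVA with Monte-Carlo Dunnett
    comparisons, 2^-ddCt fold changes, caliper tumour volumes), and a
    synthetic-screen generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
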