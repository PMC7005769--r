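Package: flexlens
Title: Concordance of Protein Flexibility, Secondary-Structure Prediction
    Error, and Disorder Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing protein flexibility seen in molecular
    dynamics simulations against the output of secondary-structure and
    intrinsic-disorder predictors. Computes a per-residue structural
    longevity statistic from trajectories of DSSP secondary-structure
    labels, a run-length-based helix/beta order score for binning protein
    chains by structured content, signed per-residue confidence profiles
    for secondary-structure predictor output, per-residue RMSF from
    coordinate trajectories with Kabsch superposition, and region-level
    concordance calls (low-longevity bands, disorder-predictor consensus,
    and discordant regions that are flexible in simulation yet silent in
    every disorder predictor). A seeded synthetic-data generator emulates
    the statistical structure of the simulation- and predictor-derived
    inputs so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
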