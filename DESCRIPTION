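Package: slowcodon
Title: Slow-Codon Window Design and Single-Cell mRNA Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how synonymous codon choice shapes mRNA
    stability under RNA interference. Designs synonymous slow-codon-window
    variants of an open reading frame, simulates ribosome traffic along the
    ORF (a totally asymmetric exclusion process with extended particles,
    codon-specific hopping rates, premature drop-off and termination) to
    obtain steady-state ribosome density profiles and fluxes, fits
    single-cell two-channel fluorescence trajectories to a three-stage
    translation/maturation/degradation model, generates synthetic
    single-cell datasets emulating live-cell imaging on single-cell arrays,
    and implements the normalization ladder, Mann-Whitney group comparisons
    and per-codon density-stability correlation profiles used to relate
    simulated ribosome occupancy to measured mRNA lifetimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
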