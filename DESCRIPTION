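Package: dropswitch
Title: Simulation and Analysis of Droplet-Sorting Riboswitch Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cell-free riboswitch screening campaigns performed by
    fluorescence-activated droplet sorting. Provides degenerate-library design
    and enumeration, closed-form and sampling models of Poisson bead
    encapsulation (with optional bead aggregation), a full stochastic
    simulator of alternating ON/OFF sorting cycles (droplet fluorescence,
    quantile gate construction, sorter errors, pool regeneration), a barcoded
    FASTQ read simulator and read-processing pipeline (demultiplexing,
    filtering, variant counting, per-cycle percentage abundance), ranking of
    variants by the enrichment-trend regression slope, and post-screen
    characterization: ROX-normalized expression, nonspecific-effect-corrected
    dose response with Hill-curve fitting, and mock-sorting efficiency,
    purity, and enrichment metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    withr,
    stats,
    generics,
    minpack.lm,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
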