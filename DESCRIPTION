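Package: nanoampsim
Title: Simulation of Nanopore Metabarcoding Long Reads with Trainable
    Error and Length Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Oxford Nanopore 16S-style amplicon (metabarcoding)
    long reads from error-free community reads. Per-read error rates follow
    an exponentiated Weibull distribution, errors are split into insertions,
    deletions and substitutions with indels biased into long homopolymer
    runs, and read lengths are reshaped into six empirical length
    categories. Includes a community amplicon fixture generator, a
    trainer that estimates all model parameters from a SAM alignment of
    real reads, and evaluation metrics (error rate, percent unmapped,
    identity, species-level precision and recall) for judging simulation
    fidelity against mock-community data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    Rcpp,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
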