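Package: regevo
Title: Simulated Evolution of Gap-Gene Regulatory Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward population simulation of transcription-factor binding
    site turnover in the regulatory sequences of the Drosophila gap genes
    hunchback, Kruppel, giant and knirps. Couples position-weight-matrix
    site annotation to a thermodynamic-occupancy / reaction-diffusion model
    of gap-gene expression, evolves populations of regulatory sequences
    under mutation, truncation selection and free recombination, tracks
    binding-site trajectories (persistence, movement, death, birth,
    rebirth), and computes binding-energy profile statistics including
    core-site and neighbour-site analyses. A fully seeded synthetic-data
    generator provides regulatory loci, motifs, accessibility masks and
    external morphogen profiles with the statistical structure the
    analysis assumes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
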