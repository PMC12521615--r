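Package: slimfit
Title: Binding Free-Energy Models for Peptide Recognition Domains from
    Display Selection Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers additive binding free-energy (-ddG/RT) models for
    peptide recognition domains, such as SH2 domains, from multi-round
    input/bound next-generation sequencing count tables produced by
    affinity selection of displayed peptide libraries.  Provides read
    processing from FASTQ to per-round count tables, maximum-likelihood
    fitting of a position-specific energy matrix with a non-specific
    background mode under a scaled binomial likelihood, an amino-acid
    log-enrichment baseline, downstream scoring of phosphosites and
    missense variants by relative affinity exp(-ddG/RT), energy-logo
    rendering, and a fully seeded simulator of library construction,
    selection rounds, and sequencing with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
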