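Package: mitoload
Title: Deleterious Mutation Load from Mitochondrial Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the deleterious mutation load segregating in
    populations (e.g. livestock breeds) from concatenated mitochondrial
    protein-coding gene alignments. Implements the Pamilo-Bianchi-Li
    counting estimator of nonsynonymous and synonymous distances with
    Kimura two-parameter correction per codon degeneracy class, per-breed
    nucleotide diversities (piN, piS) and their ratio omega_P, interspecies
    omega_S against an outgroup, the deleterious fraction
    delta = (omega_P - omega_S) / omega_P with codon-bootstrap standard
    errors, distance-based coalescence ages, and age-load association
    statistics. Ships a coalescent codon simulator with separately tunable
    polymorphism- and divergence-level omega plus GenBank-style fixture
    writers so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
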