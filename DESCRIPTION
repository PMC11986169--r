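Package: proteopick
Type: Package
Title: Proteotypic Peptide Selection and Immune-Cell Spectral Library Assembly
Version: 0.1.0
Authors@R: person("Proteopick", "Developers", role = c("aut", "cre"),
    email = "maintainer@proteopick.dev")
Description: Toolkit for designing targeted mass-spectrometry (PRM/MRM) assays
    from shotgun proteomics evidence. Performs in-silico tryptic digestion of a
    FASTA proteome, builds a proteome-wide peptide uniqueness (proteotypicity)
    index, ranks candidate peptides with an additive 11-point suitability
    score, computes NSAF relative abundance from spectral counts, validates
    and projects post-translational modification observations onto protein
    coordinates, and assembles per-cell-type spectral library tables with
    exclusive set intersections and complete-linkage marker clustering. A
    synthetic-fixture generator plants ground truth for end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    optparse,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
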