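Package: rfxcilia
Title: Comparative Survey of RFX Transcription Factors and Ciliary Gene
    Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end comparative-genomics survey pipeline for the RFX
    transcription factor family and the intraflagellar transport (IFT)
    machinery. Detects RFX DNA-binding domains (DBDs) in peptide proteomes by
    Smith-Waterman local alignment with a corrected percent-identity score,
    validates nine DNA-contact anchor residues, classifies candidates into
    RFX and RFX-like tiers, and expands the query set iteratively across
    ordered taxon groups. Scans 24 ciliary IFT/BBS query proteins per species
    into a conservation matrix, infers neighbor-joining phylogenies of
    recovered DBDs with clade assignment against reference groups, annotates
    non-DBD domain architectures with position-specific scoring profiles,
    and classifies every species into cilia/RFX co-occurrence states. Ships
    a synthetic-proteome simulator with known ground truth so every stage is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
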