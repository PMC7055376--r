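Package: kitescan
Title: Genome-Wide Survey of smc, scpA and scpB Co-Occurrence and the
    ScpA Middle-Region Length in Archaea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to survey prokaryotic genome annotations for the
    condensin subunit genes smc, scpA (kleisin) and scpB (kite), call
    presence or absence per genome by product-name string search with an
    affine-gap homology fallback and pseudogene accounting, measure gene
    juxtaposition (intervening-gene counts, flanking products), and
    aggregate per-taxon occurrence and synteny into a three-part report.
    Also computes the length of the ScpA "middle region" (the segment
    between helix alpha-3 and the next conserved helix, which carries the
    ScpB-binding interface in bacterial ScpA) by projecting reference
    residue anchors through pairwise or multiple alignments, and bins
    lengths into archaeal-like and bacterial-like classes. Includes a
    seeded synthetic-cohort generator (GFF3 + protein FASTA + ground
    truth) so every pipeline stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
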