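Package: tbmevo
Title: Comparative Evolution of Tankyrase-Binding Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative-evolution analysis of tankyrases and
    their binding partners: short-linear-motif (tankyrase-binding motif)
    scanning with alignment-anchored presence/absence classification
    across ortholog sets, reference-anchored conservation profiling of
    multiple sequence alignments with projection onto PDB structures,
    affine-gap global and local pairwise alignment with percent-identity
    reporting, neighbor-joining phylogenies with column-resampling
    bootstrap supports, and a synthetic ortholog-family simulator with
    domain/linker architecture and planted motifs that makes every
    pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
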