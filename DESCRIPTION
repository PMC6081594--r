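Package: sirscan
Title: Detection and Genomic Context Analysis of Short Inverted Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects short inverted repeats (S-IRs) capable of cruciform
    extrusion in organellar genomes, with arms of 6-60 bp, spacers of
    0-10 bp and at most one internal mismatch. Computes per-genome and
    per-group length-resolved frequency statistics, S-IR enrichment in
    and around annotated features (+/- 100 bp neighborhoods), grouping
    of abundant arm sequences by Levenshtein distance, Ward.D2
    hierarchical clustering and PCA of length-frequency profiles, and a
    synthetic annotated-genome generator with planted repeats for
    ground-truth validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
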