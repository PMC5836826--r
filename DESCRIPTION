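Package: physmapr
Title: BAC Physical Map Construction from High-Information-Content Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale construction and evaluation of BAC physical maps from
    high-information-content (HICF SNaPshot) restriction fingerprints. Simulates
    chromosome-arm BAC libraries (HindIII partial digest, size selection, 384-well
    plates, flow-sort contamination), computes five-enzyme in silico fingerprints on
    a one-dimensional encoded band scale, scores clone overlaps with the Sulston
    probability, assembles linear-topology contigs with staged questionable-clone
    exclusion, selects minimal tiling paths, anchors contigs by pooled marker
    screening, deletion bins and in silico fingerprinting of a reference
    pseudomolecule, and reports assembly statistics (N50/L50, coverage, depth,
    size-class distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
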