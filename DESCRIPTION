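Package: bacmap
Title: BAC Physical Mapping, Fingerprint Contig Assembly and Comparative
    Rearrangement Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating BAC (bacterial artificial
    chromosome) physical maps and reference-anchored comparative maps.
    Implements Sulston-type coincidence scoring of restriction
    fingerprints, FPC-style contig assembly (DQ re-assembly, end merging,
    marker incorporation, singleton adoption), seed-and-extend mapping of
    paired BAC-end sequences with mate-pair consistency classification,
    comparative contig construction along a reference genome, and
    inversion/fission detection from discordant mate-pair clusters and
    orientation segments.  A genome-rearrangement simulator (reference and
    derived genomes with ground-truth lift-over, BAC libraries, BAC-end
    reads, overgo probes) makes every stage verifiable end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
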