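Package: junctionTE
Title: Junction-Read Discovery of Non-Reference Transposable Element Insertions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers non-reference transposable element (TE) insertions from
    paired-end short reads by matching reads against a TE consensus library,
    trimming junction reads to their genomic flanks, mapping flanks and
    supporting reads to the reference genome, clustering mapped evidence into
    insertion loci, and calling target site duplications (TSDs) at single-base
    resolution. Ships a simulation benchmark: a genome mutator that plants TE
    insertions with family-specific TSDs, a seeded paired-end read simulator,
    and a scorer computing sensitivity, specificity and TSD recall under a
    100 bp matching criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
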