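Package: somagraph
Title: Somatic Small-Variant Calling by Joint Tumor/Normal Local Assembly Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale somatic small-variant caller for matched tumor/normal
    short-read data. Genomic windows are assembled jointly into a colored de
    Bruijn graph, haplotype contigs are extracted by capacity-constrained
    shortest-path traversal, candidate variants are discovered from a partial
    order alignment of the contigs against the local reference, and every read
    is re-aligned to the reference and contigs to assign allele support and
    genotypes. Candidates are scored with a glass-box cyclic additive boosting
    classifier whose predictions decompose exactly into per-feature
    contributions. Includes a seeded tumor/normal read simulator, a
    cross-platform ("two-tech") truth-set rescue classifier, and GFA export of
    the local variant graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    stringi,
    jsonlite,
    Biostrings,
    Rsamtools,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
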