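Package: centeline
Title: Mining, Dating and Centromere-Targeting Analysis of LINE Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the annotation and evolutionary analysis of
    centromere-colonizing LINE retrotransposons. The package simulates
    multi-chromosome genomes carrying planted element insertions with known
    ages, target-site duplications (TSDs), 5' truncations and nesting into
    donor elements; mines element copies from an anchor sequence by
    seed-and-extend homology search; classifies copies as full-length,
    truncated or fragmentary and scores ORF intactness; detects TSDs and
    junction base-composition bias; dates insertions from highest pairwise
    identity or LTR divergence under a linear molecular clock; quantifies
    centromere-targeting enrichment against a random-placement null; calls
    CENH3-binding domains from windowed ChIP/input read densities; converts
    fiber-FISH measurements to physical distances; and builds
    bootstrap-supported neighbor-joining trees of reverse-transcriptase
    domains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, Annotation, Alignment, Transposon
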