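Package: NucShift
Title: Nucleosome Positioning and Shift Classification from MNase-seq Fragments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anchored analysis of MNase-seq fragment data around transcription
    start sites, enhancer summits and transcription-factor motifs. Canonical
    nucleosome fragments (140-180 bp) are reduced to dyad midpoints, converted
    to normalized nucleosome center-positioning scores and smoothed with a
    Gaussian center-weighted kernel; the -1/+1 nucleosomes flanking each anchor
    are called by topographic peak prominence with bootstrap positional
    standard errors. Between-condition dyad displacements are tested with
    one-tailed z tests and anchors are classified into non-shift / Shift 1 /
    Shift 2 / Shift 3 spacing-change patterns, summarized per group and
    associated with decreased-signal region sets by one-sided hypergeometric
    tests. Library-size, spike-in and conserved-gene normalization schemes,
    background-noise correction and region-classification utilities are
    included, together with a seeded synthetic fragment generator that emulates
    positioned nucleosomes with Gaussian dyad fuzziness so the whole pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, NucleosomePositioning, FunctionalGenomics, Sequencing
RoxygenNote: 7.3.3
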