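Package: cmagkit
Title: Selection and Evaluation of Circularized Complete
    Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting circularized complete metagenome-assembled
    genomes (cMAGs) from long-read metagenome assemblies and for evaluating
    them. Implements biological-prior filtering of circular contigs
    (length, universal single-copy markers, rRNA and tRNA content),
    assembly-graph bubble and repeat screening, redundancy removal by
    whole-genome alignment (ANI and maximum alignment coverage),
    core-contig congruency filtering against a conspecific genome catalog,
    GC-skew origin/terminus diagnostics, SNV-density percentile ranking,
    per-bin genome retrieval-rate profiling, and a synthetic pangenome
    simulator with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
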