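Package: plegenes
Title: Gene-Structure Annotation and Pooled-Library Screening for the Pig Liver Esterase Gene Cluster
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the genomic organisation of the pig liver
    esterase (PLE) carboxylesterase gene family from BAC-scale sequence data:
    cDNA-guided spliced alignment under the canonical GT-AG splice-site rule,
    detection of long inverted (reverse-complement) repeat pairs in promoter
    regions, vector trimming and overlap-based ordering of BAC clones into gene
    clusters, classification of isoenzymes by their diagnostic amino-acid
    positions, and in-silico PCR with a simulation of the three-step pooled
    PCR screen of a 384-well-plate BAC library. A synthetic-data generator
    emits PLE-like gene clusters, clone sets and library layouts with known
    ground truth so that every pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    readr,
    generics,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
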