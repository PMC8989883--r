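Package: paleoshuffle
Title: Paleo-Polyploidy Karyotype Reconstruction, Ks Dating and Chromatin
    Topology Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing ancestral karyotypes from gene
    collinearity, quantifying biased fractionation of homoeologs after
    whole-genome duplications, dating duplication events from Nei-Gojobori
    synonymous-substitution (Ks) distributions fitted with Gaussian
    mixtures, classifying homoeolog expression triads across tissues, and
    comparing Hi-C A/B compartments and insulation-score TAD calls across
    duplicated genomic regions. Includes a synthetic-genome generator that
    implants a known polyploidy history (triplication, duplication,
    chromosome fusions, biased gene loss, rearrangements) together with
    expression, methylation and contact-matrix truth, so that every stage
    of the pipeline can be verified against ground truth without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
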