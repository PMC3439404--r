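Package: dartmap
Title: Linkage and Physical Mapping Characterization of DArT Marker Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize Diversity Arrays Technology (DArT)
    genotyping arrays against a reference genome: marker quality filtering
    and Mendelian segregation tests for outbred full-sib (CP) families,
    two-point maximum-likelihood linkage mapping of dominant and codominant
    markers with Kosambi distances, probe sequence redundancy clustering
    under tiered stringency presets, post-processing and classification of
    probe-to-genome alignment hits, integration of genetic and physical maps
    (collinearity, kbp/cM ratios, scaffold anchoring), and gene-space
    coverage statistics. Includes a synthetic-data generator (genomes, gene
    models, probe sets and simulated mapping populations with known truth)
    so the whole pipeline can be exercised and validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    BiocGenerics,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
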