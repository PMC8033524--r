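Package: pbscreen
Title: PiggyBac Insertional Mutagenesis Screen Analysis with Synthetic
    Splinkerette Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for in vivo piggyBac transposon
    insertional-mutagenesis screens for metastasis genes: splinkerette
    paired-end read processing (transposon-prefix trimming, unique-pair
    alignment), TTAA-anchored integration-site calling with
    PCR-duplicate-robust shear-end diversity quantification, hierarchical
    assignment of sites to genes (promoter, 5'UTR, CDS, 3'UTR, intron,
    ncRNA, intergenic), per-sample normalized insertion percentages and
    Mann-Whitney enrichment ranking of metastatic versus tumour samples.
    Also implements the surrounding quantitative procedures of such a
    screen: GREAT-style basal-plus-extension peak-to-gene association,
    log-linear tumour growth kinetics with time-to-threshold estimation,
    2^-ddCt relative qPCR quantification, ChIP-qPCR percent-input, and
    H-DAB colour-deconvolution immunohistochemistry area quantification.
    A synthetic-data module generates reference genomes, transcript
    models, planted-insertion truth tables, splinkerette FASTQ libraries,
    growth series and stained images so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
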