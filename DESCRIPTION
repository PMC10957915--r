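Package: regulomeMM
Title: Integrative Enhancer Regulome Analysis for Multiple Myeloma
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to integrate chromatin-state, ChIP-seq, expression and
    chromosome-conformation data around aberrant NF-kB signalling in
    multiple myeloma. Implements an NF-kB expression index with cohort
    classification, enhancer-origin classification from chromHMM state
    activity across B-cell, plasma-cell and myeloma samples (STABILO),
    ROSE-style super-enhancer stitching with a signal-rank tangent cutoff,
    consensus peak construction across replicates, HiChIP loop anchor
    annotation with inclusive enhancer-promoter pairing, and assembly of an
    integrated enhancer-promoter interaction master table. A synthetic-data
    generator with planted ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Epigenetics, FunctionalGenomics, GeneRegulation, ChIPSeq,
    HiC, Transcription
Config/testthat/edition: 3
RoxygenNote: 7.3.3
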