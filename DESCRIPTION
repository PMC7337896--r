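Package: erbsCluster
Title: Clustering and Activity Classification of Estrogen Receptor Binding Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of estrogen receptor alpha binding-site
    (ERBS) clusters. Merges ChIP-seq peaks into clusters with a gap
    threshold, compares clustering against subsampled control site sets,
    scans site sequences for full and half estrogen response elements
    (EREs) under a mismatch rule, flags basal H3K27ac overlap, classifies
    clusters as active and as hierarchical (MMP17-like) or synergistic
    (CISH-like), associates clusters with genes through TSS windows, and
    tests enrichment with Fisher's exact and Wilcoxon rank tests. Includes
    a synthetic regulatory-landscape generator with a machine-readable
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: ChIPSeq, Epigenetics, GeneRegulation, Transcription, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
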