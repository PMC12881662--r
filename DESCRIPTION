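Package: uraseq
Title: Genomic Uracil Enrichment and Drug-Induced Mutagenesis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of uracil-DNA sequencing (U-DNA-seq) and
    somatic mutagenesis data from thymidylate-synthase-inhibitor-treated
    cells. Rescales uracil enrichment ratio tracks to absolute
    uracil-probability tracks anchored to a measured global uracil content,
    computes gene-level U-scores and calls differentially uracilated genes
    (Welch t test with fold-change and p-value gates), derives
    allele-frequency-weighted single- and double-base substitution spectra
    (96 / 1,536 / 78 channel), refits measured spectra against reference
    signatures by non-negative least squares with cosine-similarity
    reporting, detects kataegis-like mutation clusters from intermutational
    distances, classifies substitutions by stem-loop (hairpin) sequence
    context, and summarizes tracks and variants over labeled genome
    segmentations. A synthetic-data generator with known ground truth
    (genome, genes, enrichment and replication-timing tracks, segmentations,
    variant sets) makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    pracma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
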