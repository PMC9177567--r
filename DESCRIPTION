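Package: magsv
Title: Structural-Variant Fingerprints and Associations in Gut Microbiome MAGs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for structural variation (SV) in
    metagenome-assembled genomes (MAGs) of the human gut microbiome.
    Provides MAG quality scoring and representative-genome selection,
    pairwise SV calling (insertions, deletions, inversions) from anchor-based
    whole-genome alignment with contig-end filtering and per-megabase
    normalisation, spanning-read validation with long reads,
    inter- versus intra-individual SV fingerprint statistics
    (rank-sum tests, Jaccard distances, principal-coordinates analysis,
    Procrustes permutation tests), an SV-stratified bacteria-metabolite
    association cascade (occurrence filters, Spearman screening with
    Benjamini-Hochberg FDR, SV0/SV1 subgroup dissection, covariate-controlled
    partial correlations), Fisher enrichment of SV-affected genes, and a
    synthetic-data module that generates genomes with planted SVs, ONT-like
    long reads, and cohort matrices with planted confounded associations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    data.table,
    vegan
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    rtracklayer,
    BiocGenerics,
    jsonlite
Config/testthat/edition: 3
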