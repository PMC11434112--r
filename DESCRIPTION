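Package: grainTRN
Title: Footprint-Anchored Transcriptional Regulatory Network Inference for
    Developing Cereal Endosperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-factor to target-gene regulatory networks in
    developing cereal (hexaploid wheat) endosperm by combining promoter-proximal
    accessible-chromatin motif occurrences conditioned on ATAC-seq footprints
    with tree-ensemble co-expression importance scores, and triages candidate
    regulators against GWAS intervals, expression-phenotype correlation groups
    and mutant-phenotype evidence. Also provides the surrounding descriptive
    statistics for polyploid grain development: TPM normalization, temporal
    k-means clustering, homoeolog-triad expression-balance classification,
    expression-epigenome correlation over promoter windows, background-matched
    motif-accessibility deviation scores, coefficient of variation, SNP density
    in accessible chromatin, and haplotype-trait association. A seeded
    synthetic-data generator produces a complete miniature study with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    ranger,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
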