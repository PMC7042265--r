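Package: aseqtl
Title: Allele-Specific Expression Calling, cis-eQTL Mapping and
    Enrichment Testing for Paired Genotype-Transcriptome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the bespoke statistics of paired
    genotype/transcriptome studies of bulk brain tissue: exact binomial
    allele-specific-expression (ASE) calling with per-sample false
    discovery rate control and classification of sites by consistency,
    imprinting-like behaviour and mono-allelic (nonsense-mediated decay)
    expression; evidence-tier classification of unannotated expressed
    regions using split-read junctions, co-expression and proximity to
    known genes; cis-eQTL mapping with covariate-adjusted linear models,
    per-feature FDR and stepwise conditional analysis; a beta-heterogeneity
    mixed-model likelihood-ratio test for eQTL signal sharing across a
    gene's expression features; and read-depth-matched randomization tests
    for GWAS and eQTL enrichment among ASE sites, together with module
    eigengene/membership computation and Fisher enrichment. A synthetic
    data module generates every input with planted ground truth so all
    stages are testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    yaml,
    jsonlite,
    vcfR,
    lme4,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
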