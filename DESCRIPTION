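Package: pleiocca
Title: Pleiotropic Gene Discovery from Multi-Trait GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("pleiocca", "developers", email = "pleiocca@example.org",
           role = c("aut", "cre"))
Description: A gene-centric pipeline for detecting potential pleiotropic genes
    across correlated quantitative traits using only genome-wide association
    study (GWAS) summary statistics. Per-trait effect sizes are harmonized to a
    common effect allele, SNPs are assigned to genes and pruned to
    near-independence against a reference genotype panel, and each gene is
    tested jointly across all traits with summary-level canonical correlation
    analysis built from SNP-SNP, SNP-trait and trait-trait correlation blocks.
    Genes passing a Bonferroni screen are refined with per-trait gene-based
    association tests whose linkage-disequilibrium-aware null is simulated by
    Monte Carlo, genes significant for more than one trait are flagged as
    potentially pleiotropic, and the resulting gene list is tested for gene-set
    over-representation with hypergeometric tests and Benjamini-Hochberg
    correction. A synthetic-data generator with planted multi-trait effects
    supports calibration and recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    withr
Config/testthat/edition: 3
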