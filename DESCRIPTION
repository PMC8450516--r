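Package: snpfunnel
Title: Regulatory Variant Prioritization and Two-Stage Case-Control
    Association Analysis for GWAS Loci
Version: 0.1.0
Authors@R:
    person("Jie", "Lang", email = "jlang@example.org", role = c("aut", "cre"))
Description: Tools for fine-mapping putatively regulatory single-nucleotide
    polymorphisms within genome-wide association study (GWAS) loci and for
    evaluating them in a two-stage case-control design. The prioritization
    funnel tiers tag SNPs by significance, expands each locus through
    pairwise linkage disequilibrium estimated by an EM algorithm on an
    unphased reference panel, and intersects the expanded variant set with
    open-chromatin (ATAC-seq) and histone-mark (H3K27ac ChIP-seq) peak
    intervals. The association engine provides Hardy-Weinberg and call-rate
    quality control, Pearson chi-square tests, crude and covariate-adjusted
    odds ratios under five genetic models (homozygous, heterozygous,
    dominant, recessive, additive), a screen-and-validate two-stage
    workflow with pooled combined analysis, and stratified analyses. A
    synthetic-data module generates haplotype panels with controlled
    linkage disequilibrium, peak sets with planted variant overlaps, and
    case-control cohorts with known genetic and covariate effects, so every
    stage of the pipeline can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
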