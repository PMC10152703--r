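Package: svcurate
Title: Post-Discovery Curation and Population QC of Structural Variant Call Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to curate raw structural-variant (SV) call sets from
    short-read cohort sequencing using per-sample read-depth fold-coverage
    annotations (DHFFC/DHBFC). Implements a genotype-conditional depth-filter
    cascade producing a clean call set, classification of clean calls into
    stringent, lenient and multi-allelic CNV (mCNV) tiers, trio-based
    Mendelian-error quality metrics, CNV-SNP linkage-disequilibrium tagging
    analyses, and classification of coding-sequence disrupting SVs into
    predicted loss-of-function, copy-gain and intragenic exonic duplication
    classes. A pedigree-aware synthetic cohort generator with genotype-
    conditional fold-coverage, injected artifacts, multi-allelic loci and
    SNPs in tunable LD makes the full pipeline testable without sequence
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StructuralVariation, CopyNumberVariation, QualityControl,
    VariantAnnotation, Genetics
RoxygenNote: 7.3.3
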