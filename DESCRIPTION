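Package: rootQTL
Title: Dissection of Small-Effect Root-Trait QTLs in Structured Rice Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for mapping and prioritising small-effect
    quantitative trait loci (QTLs) for root traits in structured inbred
    panels such as rice diversity collections. Provides structure-corrected
    association scans (fixed-effect models with principal-component
    covariates and a compressed kinship mixed model), a conditional
    permutation test that sets a genome-wide significance threshold while
    preserving the population-structure component of the phenotype,
    SNP-cluster QTL interval calling, extreme-pool allele-frequency
    chi-square screening, multi-evidence candidate-gene shortlisting
    (linkage-interval intersection, variant-effect annotation, expression
    filters), gene-level haplotype-phenotype tests with Duncan multiple
    range grouping, and a population-genetic adaptation scan (nucleotide
    diversity ratios, Tajima's D, trait-increasing allele pyramiding,
    neighbor-joining trees). A fully specified synthetic-panel generator
    with planted causal genes makes every stage testable end to end.
License: MIT + file LICENSE
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
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
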