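Package: dmafpanel
Title: Low-Density SNP Panel Design and Validation from Multi-Population
    Genotypes
Version: 0.1.0
Authors@R: person("Panel", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Designs small "liquid chip" (genotyping-by-target-sequencing)
    SNP panels that discriminate closely related livestock populations, and
    validates them. From a multi-population VCF it applies site-level quality
    filters, computes per-population allele frequencies and pairwise
    allele-frequency differentials (delta-MAF), gates candidate sites on
    hybridization-probe feasibility (flanking GC content and genomic k-mer
    uniqueness), assembles the panel by per-population top-K union with
    autosome-favoring capacity allocation and detection-rate pruning, and
    validates the result with per-sample genotype statistics, a genomic
    relationship matrix PCA, identity-by-state distances and a
    neighbor-joining tree. A hierarchical Balding-Nichols simulator generates
    multi-breed cohorts, reference genomes and gene models so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ape,
    BiocGenerics,
    Biostrings,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
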