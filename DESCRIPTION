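Package: snpforge
Title: SNP Array Construction and Population Genetic Validation for
    Non-Model Species
Version: 0.1.0
Authors@R:
    person("snpforge", "maintainers", email = "snpforge@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline from raw discovery variant calls to an
    array-ready SNP catalog and onward to population-genetic inference.
    Implements simultaneous SNP-exclusion filter tags (genotype-confidence
    nulling, indel proximity, SNP clusters, low-complexity and homopolymer
    regions, hard-filter annotations, haploid-consistency, single-probe
    allele compatibility), 71-base probe extraction with 16-mer frequency
    screening, Axiom-style genotyping QC classification (PHR/MHR/NMH/CRBT),
    and the population statistics used to validate such arrays: observed
    and unbiased expected heterozygosity, Weir-Cockerham inbreeding and
    differentiation estimators with bootstrap confidence intervals,
    hierarchical allele-level AMOVA with permutation tests, pairwise Fst,
    principal coordinate analysis, site frequency spectra, random SNP
    subset resampling and the Evanno delta-K statistic. A synthetic-data
    module generates discovery references, VCFs and genotype matrices
    under a two-level hierarchical island model with planted ground truth
    so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
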