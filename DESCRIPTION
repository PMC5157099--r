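Package: tumorcn
Title: Tumor Purity, Ploidy, Allele-Specific Copy Number and SNV
    Classification from Targeted Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates tumor purity and ploidy from hybrid-capture
    sequencing coverage, assigns allele-specific integer copy number and
    loss of heterozygosity to segments, and classifies single-nucleotide
    variants as somatic or germline (with clonality) with or without a
    matched normal sample. Combines GC and pool-of-normals coverage
    normalization, weighted circular binary segmentation refined by
    germline allelic fractions, a 2D purity/ploidy grid search with
    heated Gibbs assignment of integer copy states, and a joint
    copy-number and beta-likelihood allelic-fraction model for variant
    posteriors. Includes a benchmarking-grade simulator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    Rcpp,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
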