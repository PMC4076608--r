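Package: crossmeth
Title: Allele-Resolved Differential Methylation Analysis for Reciprocal
    Inbred Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of reduced representation bisulfite sequencing (RRBS)
    data from reciprocal crosses of inbred mouse strains. Calls SNPs from
    pooled bisulfite base counts, assigns sequencing reads to parental
    alleles and parents of origin, and detects strain-specific, allele-
    specific, sex-specific and imprinted methylation with exact binomial
    confidence-interval and group t-test screens calibrated by
    simulation-based false discovery rates. Scans read-level methylation
    patterns for allelically methylated regions with a two-allele mixture
    likelihood, detects intergenerational epimutations between parental and
    F1 chromosomes, and validates imprinting with allelic expression counts.
    Includes a ground-truthed synthetic data generator emulating the
    eight-sample reciprocal cross design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
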