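Package: radsnp
Title: RAD-Tag SNP Discovery, CAPS Conversion and Linkage Toolkit
Version: 0.1.0
Authors@R:
    person("radsnp", "developers", email = "radsnp@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of restriction-site associated DNA (RAD)
    sequencing experiments for SNP marker discovery in heterozygous diploids.
    Generates three-parent RAD libraries with known ground truth, clusters
    restriction-anchored single-end reads and assembles per-locus reference
    contigs under coverage and quality filters, aligns paired reads to call and
    classify testcross/intercross SNP markers, computes CpG-stratified k-mer
    spectra and the Karlin-Mrazek CpG rate, converts SNPs to CAPS (cleaved
    amplified polymorphic sequence) assays with restriction-fragment
    prediction, and performs chi-square segregation tests plus two-point
    linkage grouping with Kosambi map distances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
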