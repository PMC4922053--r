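Package: asmrefine
Title: Assembly Refinement Toolkit for Fosmid-Pool Genome Projects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for refining draft genome assemblies built from
    whole-genome shotgun and fosmid-pool sequencing data: k-mer spectrum
    profiling (peak detection, genome-size and heterozygosity estimation),
    insert-size distribution modelling with short-insert contaminant
    filtering, read-pair consistency scoring with scaffold breaking at
    net-negative regions, overlap-layout-consensus merging of multiple
    partially redundant assemblies with haplotype collapsing and tip
    merging, decontamination masking and read-partitioning filters,
    homozygous-variant polishing, a fosmid clone-pool simulator with
    Lander-Waterman closed forms, and gene-duplication diagnostics based
    on reciprocal best hits and heterozygous SNV counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    vcfR,
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
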