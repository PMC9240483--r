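Package: bsascan
Title: Bulked Segregant Analysis Genome Scans with SNP-Index and
    Euclidean Distance Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for QTL mapping by bulked segregant analysis of
    pooled whole-genome sequencing (BSA-seq). Reads a four-sample
    variant table (two inbred parents plus two phenotypically extreme
    F2 bulks), applies the per-method SNP filtering ledgers, computes
    per-site SNP-index, delta SNP-index and Euclidean-distance
    statistics from allele depths, fits them in sliding windows along
    the genome, builds Monte-Carlo and summary-statistic significance
    thresholds, and calls and intersects candidate trait-associated
    regions with optional gene-content annotation. Includes a full
    F2-cross simulator (Mendelian segregation under the Haldane map
    function, additive QTL phenotypes, extreme-bulk selection, pooled
    read sampling, VCF output) so every stage of the pipeline can be
    exercised against known ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
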