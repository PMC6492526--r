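Package: xenoSNP
Title: Cross-Species SNP Array Transfer: Genotype Quality Filtering,
    Flank-Sequence Validation and Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering single-nucleotide polymorphisms in a
    target species genotyped on a SNP array designed for a related
    species. Implements per-SNP quality metrics (call frequency, GenCall
    score percentiles, average GC, GenTrain thresholds), configurable
    filter-method cascades, exact-match validation of probe flanking
    sequences against reference genome assemblies, locus uniqueness
    classification and cross-assembly intersection, Hardy-Weinberg
    testing, scaffold-to-chromosome synteny assignment, nearest-gene
    annotation, derived-statistic reporting, and a synthetic-data
    generator with planted ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
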