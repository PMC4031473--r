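Package: chipcoop
Title: Transcription-Factor Co-Occupancy and Knockdown-Response Analysis of
    ChIP-Seq Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of transcription-factor and chromatin-regulator
    ChIP-seq peak sets with knockdown expression data. Assigns peaks to target
    genes by a strand-aware window around transcription start sites, quantifies
    multi-factor co-occupancy (interval overlap, solo/ensemble peak partition,
    hypergeometric significance of target-set overlap), builds anchor-centred
    signal profile matrices, runs microarray-style differential expression
    (background correction, quantile normalization, per-gene Student t-tests,
    Benjamini-Hochberg adjustment), infers activator/repressor roles from
    one-sided Kolmogorov-Smirnov comparison of peak-to-TSS distance
    distributions with regulatory-potential scoring, checks known-motif (PWM)
    enrichment in summit-centred windows, and ships a seeded synthetic-data
    generator with ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    limma,
    methods,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
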