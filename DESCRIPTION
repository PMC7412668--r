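Package: srmeth
Title: Single-Read Analysis of CHH Methylation Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyses bisulfite-sequencing data at single-read resolution to
    characterise non-CG (CHH) methylation. Segments annotated elements into
    short per-strand regions with a fixed number of cytosine context sites,
    extracts per-read binary methylation vectors from aligned reads, and
    computes three variation features (among-site variation, read-methylation
    variation, and within-read stochasticity). A per-site Bernoulli null model
    separates stochastic from regulated variation, and an ordinary
    least-squares pattern-score classifier on the region features
    distinguishes DRM2-like (bimodal, low-stochasticity) from CMT2-like
    (unimodal, high-stochasticity) methylation activity, evaluated by ROC
    curves and kernel-density peak counting of genome-wide score
    distributions. Includes a bisulfite read simulator producing complete
    FASTA/GFF3/SAM fixtures under both regimes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
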