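Package: regupeaks
Title: Transcription-Factor Binding-Site Analysis with Dimeric Motif
    Scanning, Peak Annotation, Conservation Scoring, and Disease-Phenotype
    Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide analysis of transcription-factor
    binding sites from ChIP-seq peaks, modelled on the analysis of
    p53-family factors such as p63. Provides dimeric position-weight-matrix
    construction and scanning with f-measure-calibrated score thresholds
    and background-based false-discovery-rate estimates; a de novo motif
    significance pipeline using hypergeometric enrichment against dual
    (genomic and Markov) backgrounds with Benjamini-Hochberg correction;
    genomic-category peak classification and potential-target-gene mapping;
    per-region conservation-score averaging with cumulative cut-off curves;
    CTCF-delimited candidate-enhancer search; disease-phenotype similarity
    statistics with resampling nulls; and synthetic-data generators with
    ground-truth tables so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
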