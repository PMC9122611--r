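Package: spliceRELI
Title: Resampling-Based RNA-Binding-Protein Enrichment Around Differentially
    Spliced Cassette Exons
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies cassette exons differentially spliced between two
    conditions from inclusion/skipping junction read counts using a Beta
    posterior on percent-spliced-in (PSI), and ranks RNA-binding-protein
    CLIP peak datasets by positional association with those exons via a
    resampling-based enrichment test (an RBP-oriented RELI-style analysis):
    an empirical null is built by repeatedly sampling expressed-but-unchanged
    background exons, intersection counts are converted to Z-scores,
    one-sided P-values, enrichment (observed over expected) and a
    merged-region binding-frequency ratio, with Benjamini-Hochberg correction
    and a triple significance cutoff. Includes rMAPS-style positional motif
    maps (sliding-window motif density with per-position rank-sum tests) and
    a fully deterministic synthetic-data generator (genome, junction counts,
    planted CLIP regulators and planted motifs) so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
biocViews: AlternativeSplicing, RNASeq, MotifAnnotation, Software
RoxygenNote: 7.3.3
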