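Package: chipmotif
Title: Integrated ChIP-Seq Peak Calling, De Novo Motif Discovery and
    Motif Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for transcription-factor ChIP-Seq
    analysis. Binding events are estimated from directional read data by
    maximum a posteriori EM fitting of a truncated t-mixture model with
    read-mappability correction, control-relative enrichment scores and
    an exchange-based false discovery rate. De novo motifs are discovered
    by a genetic algorithm over spaced dyads with ZOOPS expectation-
    maximization refinement, exact PWM score p-values by dynamic
    programming, log-E-value fitness, and iterative masking; a seeded
    mode refines a user-supplied matrix directly. Discovered motifs are
    annotated against reference databases (TRANSFAC and JASPAR flat
    formats) with extreme-value-calibrated similarity E-values, virtual
    motif combination, and distance-to-peak and pairwise-distance
    statistics for cis-regulatory module analysis. A synthetic-data
    module generates directional reads around planted binding events and
    background sequences with planted PWM sites so that every stage can
    be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
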