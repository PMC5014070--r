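Package: cgram
Title: Hierarchical Dictionary Compression of Discrete Behavioural Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers compressive motifs (c-grams) in discrete behavioural
    sequences by iterated dictionary compression under a minimum description
    length criterion, and uses compressibility as a quantitative behavioural
    phenotype. Provides posture-template discretization and non-uniform time
    warping of label streams, the offline compressive heuristic with lossless
    decoding, arc diagrams and nesting dendrograms of the induced dictionary,
    null-sequence controls (uniform random, deterministic cycle, shuffled,
    sorted, first-order Markov), chunked compressibility-versus-dwell-time
    phenotyping, and FDR-controlled comparison of motif frequencies across
    experimental conditions. A synthetic-cohort generator with planted motifs
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
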