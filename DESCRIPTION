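Package: aptML
Title: Machine-Learning-Guided Particle Display Screening for DNA Aptamers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for machine-learning-guided particle display (PD) screening
    of DNA aptamer libraries. Provides a particle-display simulator with a
    ground-truth affinity oracle (binding occupancy, fluorescence-gated
    sorting across a stringency ladder, multi-round enrichment, sequencing
    count sampling, and dissociation-constant fitting); Levenshtein-based
    sequence clustering with a 6-mer inverted-index candidate stage;
    stringency pool labeling (ternary and SuperBin summaries) with
    cluster-respecting train/test splits; neural-network sequence-to-affinity
    models in three output formulations (Counts with a latent-affinity head,
    Binned, SuperBin); model-guided mutation walks with a random-walk
    baseline and in-silico seed screening; and core-sequence (truncation)
    scanning with a differential k-mer enrichment motif screen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    igraph,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
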