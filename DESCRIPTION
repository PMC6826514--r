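Package: genofabric
Title: Expression Variability and Coordination Analysis of Replicated
    Transcriptome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the organisation of a transcriptome beyond
    differential expression: spot-level validity filtering and iterative
    intra-/inter-array median normalization for two-colour microarray data,
    the redundancy-corrected Relative Expression Variability (REV) estimator,
    replicate-level Pearson expression coordination with redundancy-aware
    degrees of freedom and significance classification, coordination-reversal
    detection across conditions, pair-wise relevance (PWR) scoring of gene
    pairs against fabric-wide reference means, and signed coordination
    networks.  Includes a seeded synthetic-data generator emulating a
    replicated two-colour microarray design with programmable variability and
    latent-factor coordination structure, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
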