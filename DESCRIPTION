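Package: agealign
Title: Cross-Species Process-Level Ageing Signatures, Disease Alignment
    and Shared Risk-SNP Antagonism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for process-level analysis of transcriptomic ageing
    across species: maps expression onto gene-set (process) activities,
    applies quantile and per-stratum rank normalization, detects
    ageing-regulated processes by unbalanced type-II ANOVA with
    assumption filtering and marginality-respecting backward selection,
    and scores the alignment of ageing signatures with disease expression
    signatures (AMDA scores) together with per-process disease alignment
    contribution (DAC) scores. A companion module classifies risk SNPs
    shared between disease categories as synergistic or antagonistic,
    counts independent loci and tests for antagonism bias. Synthetic-data
    generators with serialized ground truth make the full pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
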