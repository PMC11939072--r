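Package: rbnsig
Title: Proteogenomic Discovery and Scoring of RB1-Loss Transcriptional Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and applying "RBness" transcriptional
    signatures: per-sample RB1 functional-status calling from protein,
    phospho-site, mutation and copy-number evidence; subsampling-robust
    differential expression (leave-one-out moderated t over all defective x
    proficient sample-pair deletions); multiscale Spearman relevance-network
    signature refinement; sign-alignment scoring and three-way sample
    classification; pan-cancer core-signature aggregation; and gating filters
    for CRISPR gene-effect and drug-response screens. Includes a synthetic
    cohort generator with planted RB1-defective and phenocopy structure so the
    full pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
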