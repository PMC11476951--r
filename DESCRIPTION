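Package: zfpkit
Title: Annotation and Cross-Tissue Expression Profiling of C2H2 Zinc-Finger Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide characterization of C2H2 zinc-finger
    protein (ZFP) families from domain-scan output: parsing HMMER3 per-domain
    tables, effector-domain group classification (KRAB, BTB/POZ, SCAN, SET,
    Homeodomain, PHD) with rule-based canonical-isoform selection, detection
    of genomic ZFP gene clusters by distance merging, orthologue-conservation
    summaries across target species, per-position alignment conservation
    scoring via Jensen-Shannon divergence, and a cross-tissue expression
    pipeline (TPM, abundance filtering, TMM normalization, hierarchical
    sample clustering, one-vs-rest tissue-specificity calling by a
    negative-binomial Wald test, and binomial gene-group enrichment).
    Includes synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
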