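Package: cnvconsensus
Title: Caller-Agnostic Consensus Integration of Whole-Exome CNV Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates copy-number-variation (CNV) segment calls from several
    whole-exome CNV detection tools into caller-multiplicity consensus regions
    (unique, double, triple, tetrad support), maps genes into those regions by
    a coverage-fraction rule, performs one-sided Fisher's-exact-test term
    enrichment against user-supplied gene-set catalogs, and benchmarks single
    versus integrated calling against truth CNV profiles with base-level
    TPR, FDR and precision. A seeded noise-model simulator generates truth
    profiles and per-caller call sets that emulate the size preferences of
    common exome CNV callers, so the whole pipeline is testable without
    external data. Includes readers for configurable tab-separated segment
    dialects, BED gene models and GMT gene-set catalogs, deterministic TSV
    outputs and a self-contained HTML report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    stats,
    utils,
    parallel,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
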