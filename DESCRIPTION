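Package: enhancerdyn
Title: Hormone-Induced Enhancer H3K27ac Dynamics, Chromatin Accessibility
    and Motif Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing steroid-hormone-induced enhancer dynamics
    from paired-condition ChIP-seq and FAIRE-seq coverage tracks. Identifies
    candidate enhancers from H3K4me1 peaks distal to transcription start
    sites, quantifies input-normalised H3K27 acetylation signal in fixed
    windows around enhancer summits, classifies enhancers into
    increasing/constant/decreasing/no-response categories by fold change and
    quartile gates, computes accessibility meta-profiles around summits and
    per-enhancer accessibility changes, scans enhancer sequences for known
    motifs (position weight matrices and IUPAC consensus) with hypergeometric
    per-category enrichment, classifies differentially expressed genes and
    relates their H3K27ac changes, and implements common bench quantification
    formulas (delta-delta Ct, ChIP-qPCR percent input, dual-luciferase fold,
    FAIRE-qPCR recovery ratio). A seeded synthetic-data generator emulates the
    statistical structure of a paired-condition hormone-response experiment so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    data.table,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
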