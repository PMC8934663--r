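Package: crisprkp
Title: Position-Specific Mononucleotide Feature Analysis and Scoring of
    CRISPR-Cas9 Guide RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses on-target cleavage efficiency of CRISPR-Cas9 crRNAs as a
    function of protospacer and PAM sequence. Fits position-specific
    mononucleotide feature models by efficiency-weighted two-sample Student's
    t tests at every (position, nucleotide) cell of the 23-nt target
    (20-nt protospacer plus NGG PAM), with per-position Bonferroni
    significance flags. New guides are scored by summing signed -log10
    p-value feature contributions (the CRISPR-kp score). Includes evaluation
    utilities (Pearson/Spearman benchmarking against measured indel
    frequencies and external design-tool scores, activity-class counts,
    GC-content and strand tests) and a seeded synthetic guide-set generator
    with planted position-specific effects for power and calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
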