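Package: racetails
Title: Tail Calling and Nucleotide-Addition Profiling from 3'-RACE-seq,
    with Fluorescence Anisotropy Binding Fits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for profiling nontemplated nucleotide
    addition by terminal nucleotidyltransferases. Calls added 3' tails
    from 3'-RACE-seq reads by exact-match substrate-prefix and adapter
    anchoring, attributes substrate-encoded terminal nucleotides, and
    summarises tail length distributions and 3'-anchored per-position
    nucleotide composition under a coverage rule. Also fits one-site
    saturation binding (Kd) and a global competition binding model
    (shared IC50 with per-experiment anisotropy plateaus) to fluorescence
    anisotropy titrations, with asymptotic standard errors and
    delta-method confidence bands. A synthetic-data module generates
    FASTQ read sets and anisotropy titrations with known ground truth,
    including analytic oracles for expected tail composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
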