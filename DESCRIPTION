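Package: retrotrap
Title: Design and Analysis of Insertion-Trap Screens for Germline L1
    Retrotransposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative inference for single-molecule insertion-trap
    screens that search sperm DNA for de novo LINE-1 (L1)
    retrotransposition events. Provides Poisson maximum-likelihood
    estimation of amplifiable-molecule concentrations from
    limiting-dilution PCR well data with profile-likelihood confidence
    intervals, deterministic molecule accounting through multiplex PCR
    and hybridization enrichment, conversion of a zero-event screen into
    an exact Poisson upper bound on the germline insertion frequency,
    target-locus suitability screening (probe cross-hybridization,
    endonuclease-site density, repeat-free primer windows), a structural
    classifier that annotates candidate amplicons as genuine
    target-primed reverse transcription insertions versus PCR
    template-switch chimeras, and a ground-truthed synthetic-data
    generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
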