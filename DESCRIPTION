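Package: isocurate
Title: Curation of Full-Length Spliced Isoforms from Long-Read Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates long-read transcript models against short-read splice-junction
    evidence, classifies them relative to a reference annotation (FSM, ISM, NIC,
    NNC, antisense, intergenic), consolidates near-duplicate isoforms under
    boundary tolerances, annotates ORFs, nonsense-mediated decay, transposable
    element, CAGE and polyA features, and calls tumor-specific and
    tissue-specific transcripts from TPM expression matrices using an
    entropy-based specificity score. Includes a deterministic synthetic-fixture
    generator with planted truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
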