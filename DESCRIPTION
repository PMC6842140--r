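Package: srasampler
Title: Online Greedy Sampling of RNA-Seq Sequencing Runs for Complementary
    Transcript Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selects which RNA-Seq sequencing runs of an archive to sample
    next so that a fixed download budget covers as many transcribed genome
    regions as possible. Implements an online greedy algorithm over a
    log-coverage objective on fixed-size genome tiles, with multinomial
    run-profile estimation under pseudocount smoothing, alignment-quality
    weighting and blacklisting of poorly alignable runs. Ships a
    deterministic simulator of an SRA-like archive with ground-truth gene
    models so the whole pipeline is testable offline, and an intron-level
    sensitivity/specificity evaluation of spliced alignments against a
    reference annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
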