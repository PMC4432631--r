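Package: promotrap
Title: Simulation of Promoter-Trap Reporter Libraries on Annotated Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models promoter GFP-trap libraries built from randomly sheared
    genomic DNA. Given an annotated (real or synthetic) prokaryotic genome
    with transcription-unit topology, the package predicts the fraction of
    library inserts that drive reporter expression under different trap-vector
    modes (promoterless or with an upstream inducible promoter) and
    sigma-factor promoter-recognition models, by exact enumeration over all
    fragment placements and by seeded Monte Carlo over sheared inserts. It
    also provides the Clarke-Carbon clone-number statistics used to size
    genomic libraries (required clones, fold coverage, coverage probability)
    together with survival-rate and RPKM helpers, a synthetic annotated-genome
    generator for self-contained testing, and GFF3/BED interval input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
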