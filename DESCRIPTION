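Package: asmqc
Title: Genome Assembly Evaluation: Contiguity, Alignment Validation and
    Multi-Metric Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates de novo genome assemblies in the style of the
    community assembly benchmarking exercises. Computes contiguity
    statistics (N50, NG50, NG graphs, cumulative length plots,
    gene-sized scaffold content), alignment-based validation metrics
    (coverage, validity, multiplicity and parsimony from coverage
    islands on a trusted reference), validated-region tag-pair accuracy
    scores, a paired-read consistency summary score, and multi-metric
    z-score rankings with leave-one-out bounds. Includes a synthetic
    assembly-corruption simulator with analytically known ground truth
    so every metric can be verified without external data, and a
    subcommand CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
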