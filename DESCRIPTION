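Package: shallowcn
Title: Copy Number Profiling and Concordance Analysis for Low-Coverage
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Read-depth copy number analysis for shallow (0.1-3x)
    whole-genome sequencing of low-input and FFPE-derived DNA. Bins read
    counts on a fixed genomic grid, normalizes for GC content against a
    diploid baseline, segments log2 ratios by circular binary segmentation
    with a permutation test, calls gains and losses at a +/-0.15 log2
    threshold after blacklist masking, and scores sample noise with the
    MAPD metric. Includes base-pair concordance and shared-region
    accounting between profiles, correlation clustering of bin counts in
    altered regions, count down-sampling and whole-genome-amplification
    style degradation, and a negative-binomial simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
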