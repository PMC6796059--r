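Package: scmosaic
Title: Single-Cell Shallow Sequencing Copy-Number and Mosaicism Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Copy-number analysis of single-cell shallow whole-genome
    sequencing data for the quantification of low-level chromosomal
    mosaicism in cell cultures. Binned read counts are GC-normalized,
    smoothed, segmented with circular binary segmentation, and scaled to
    absolute copy number by a sum-of-squares integer fit; per-sample bin
    size (0.5/1/2.5 Mb) is chosen by the clustering of bins around integer
    copies, CNVs are called by consecutive-bin and minimum-size thresholds,
    breakpoints are annotated against a fragile-site catalogue, and
    per-cell calls are aggregated into cohort-level mosaicism statistics
    and bulk copy-number predictions. A synthetic-data generator emulates
    whole-genome-amplification count noise (gamma-mixed multinomial
    counts with GC bias) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    IRanges,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
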