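Package: agesfs
Title: Age-Adjusted Site Frequency Spectra and Selection Inference for
    Transposable-Element Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify purifying selection on transposable-element
    (TE) insertion polymorphisms from population resequencing panels. The
    package reads combined TE/SNP variant tables, applies standard hard
    filters, polarizes alleles against an outgroup clade, and computes the
    age-adjusted site frequency spectrum: allele-age bins with equal numbers
    of focal observations, age-matched down-sampling of neutral sites, and
    the per-bin difference in mean allele frequency (delta frequency) with a
    resampling-based Wilcoxon/Bonferroni test battery. A forward
    Wright-Fisher simulator with partial selfing, recombination and mixed
    neutral/selected mutation streams (written in C++) supports two
    inference procedures: a screen for the maximum proportion of neutrally
    evolving focal mutations compatible with the observed spectrum shape,
    and estimation of the scaled selection coefficient from the ages of the
    oldest surviving mutations. A parametric synthetic-data generator with
    transposition bursts, demographic change and age-estimate noise makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    generics,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
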