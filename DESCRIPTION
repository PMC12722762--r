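Package: premark
Title: Promoter H3K4me3 Dynamics Across Gametes and Early Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for promoter-centric analysis of H3K4me3 chromatin dynamics
    across spermatid, sperm, pre-ZGA and post-ZGA stages and their relation to
    gene-expression dynamics at zygotic genome activation (ZGA). Quantifies
    promoter signal from coverage tracks (oriented TSS signal matrices,
    enrichment, peak breadth and asymmetry, CpG/GATC density, GATC-normalized
    accessibility), classifies binarized peak-presence patterns into
    SHARED/GAINED/LOST/ABSENT/FLUCTUATING groups and expression dynamics into
    GZ/GS/ZS/ND groups with first-detection timing, tests group associations
    with one-sided Fisher grids under FDR control, builds replicate-consensus
    peak sets with spike-in scale factors, calls differentially marked or
    expressed features, and ships a fully synthetic data generator with planted
    ground truth for end-to-end validation.
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
    readr,
    stringr,
    ggplot2,
    stats,
    generics,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
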