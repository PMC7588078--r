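Package: sortscreen
Title: Analysis and Simulation of FACS-Sorted Pooled CRISPRi Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hit calling for pooled CRISPR interference screens read out by
    fluorescence-activated sorting of a reporter into low, medium and high
    fractions. Counts sgRNAs from raw reads by spacer matching, computes
    per-sgRNA log2 fold changes of normalized frequencies between sorted
    fractions, scores genes by the epsilon phenotype score (mean of the three
    most extreme sgRNAs, centered on non-targeting controls) together with a
    Mann-Whitney U p-value against the non-targeting control distribution, and
    thresholds the product of the two ("hit strength") at an empirical false
    discovery rate estimated from resampled non-targeting "quasi-genes".
    Includes a generative simulator of sorted reporter screens with known
    ground-truth gene effects for end-to-end verification, classification of
    hits into high-confidence and putative sets across pairwise fraction
    comparisons, and volcano-plot output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
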