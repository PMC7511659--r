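Package: circquant
Title: Quantification and Comparative Profiling of Plant Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy workflow for quantifying circular RNAs (circRNAs) from
    back-spliced junction read counts in bulk RNA-seq, built around a droplet
    digital PCR (ddPCR) anchor. Implements six normalization schemes for
    back-spliced counts (library size, back-spliced sum, median-of-ratios size
    factors, composition-corrected variants, and an endogenous marker gene),
    Poisson-based ddPCR quantification with a replicate-dispersion limit of
    quantification, concordance evaluation of normalizations against ddPCR by
    Pearson correlation, detection-threshold calibration, candidate filtering
    (read support, two-caller confirmation, abundance), replicate and organ
    overlap set analyses, percentile-based abundance classes with clustered
    ordering, pairwise differential accumulation, circular-versus-linear
    transcript comparison, and a synthetic-data generator with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
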