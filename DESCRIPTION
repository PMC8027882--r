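Package: sipcall
Title: Active-Community Analysis for DNA Stable-Isotope Probing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying actively growing microorganisms in DNA
    stable-isotope probing (DNA-SIP) experiments with paired 13C-labeled
    incubations and 12C controls. Implements rarefaction, pooling of density
    gradient fractions, 12C-control normalization with zero-flooring,
    activity classification by one-sided Fisher exact tests, guild-level
    summaries for methanogens and methanotrophs, multigroup land-use
    comparisons (one-way ANOVA with Tukey-Kramer post hoc tests), and
    community-level permutation statistics (Bray-Curtis dissimilarity,
    PERMANOVA, PERMDISP). A synthetic SIP-experiment generator with known
    ground truth supports calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
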