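Package: allomethyl
Title: Methylome Trajectories in Allopolyploid Arabidopsis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for tracking DNA methylation dynamics
    across the formation and evolution of allopolyploids, modelled on the
    Arabidopsis suecica system (two parents, an F1 hybrid, two resynthesized
    allotetraploids and the natural allotetraploid). It reads per-cytosine
    bisulfite counts, harmonizes shared conserved cytosines across lines,
    calls context-specific differentially methylated regions (DMRs) in 100-bp
    windows with Fisher's exact test and Benjamini-Hochberg FDR control,
    classifies cross-generation DMR trajectories (convergent, conserved,
    persistent), links DMRs to genes and expression (log2 TPM ratios,
    Mann-Whitney tests, methylation-expression correlation, homolog
    convergence), and dates LTR retrotransposon insertions with the
    Jukes-Cantor correction. A synthetic six-line cohort generator with
    planted DMR trajectories and coupled expression provides a fully
    controlled test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
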