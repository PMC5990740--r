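Package: enamelgrowth
Title: Incremental Growth Analysis of Tooth Enamel and Dentine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing incremental growth lines in tooth
    sections. Provides a forward model of enamel and dentine deposition
    that produces ground-truthed synthetic sections and rendered band
    images; estimators of daily secretion rate (DSR) and crown extension
    rate (CER) by the cumulative-length method along the
    enamel-dentine junction; a test of the temporal periodicity of
    long-period incremental lines against dentine von Ebner lines; and a
    phylogenetically informed multi-group comparison of growth rates
    (phylogenetic generalized least squares for body-mass correction,
    Box-Cox transformation, MANOVA with Wilks' lambda, univariate
    ANOVAs, Kruskal-Wallis and Dunn tests, all with false discovery
    rate correction).
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    MASS,
    nlme,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
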