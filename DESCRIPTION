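Package: crossdeg
Title: Cross-Study Differential-Expression Meta-Analysis by Sign Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links differential-expression results across studies and species
    through curated homology: builds paired log2 fold-change sets between a
    seed contrast (e.g. tame versus aggressive rat hippocampus) and partner
    contrasts (e.g. hypertensive versus normotensive subjects), runs a
    correlation battery (Pearson, Spearman, Kendall, Goodman-Kruskal gamma),
    a seeded bootstrap principal-component decomposition of the paired log2
    values, per-seed-gene exact binomial sign-concordance tests with
    Bonferroni correction, and 2x2 directional contingency contrasts (Fisher
    exact, Pearson chi-square, exact binomial). Also provides a light
    differential-expression caller for two-group expression matrices, qPCR
    relative-expression summaries with exact Mann-Whitney tests, and seeded
    synthetic-data generators emulating every input the pipeline consumes.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
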