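Package: qpcrcb
Title: Common Base Analysis of qPCR Relative Expression with Regression
    and ANCOVA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Relative-expression analysis of quantitative PCR (qPCR) data
    by the common base method for unpaired designs under the general
    linear model. Converts quantification cycles and amplification
    efficiencies into efficiency-weighted, reference-normalized delta-Cq
    values on a base-10 log scale; fits ordinary least-squares regressions
    of delta-Cq against covariates, responses, or a second gene's
    delta-Cq (with optional log transforms of either axis); transforms
    fitted slopes into relative-expression or response curves with
    confidence bands propagated from the slope confidence interval; and
    performs one-way ANCOVA with a homogeneity-of-slopes test, a common
    slope fit, and pairwise expression-ratio contrasts. Includes embedded
    hypothetical example tables, a seeded synthetic-data generator, and a
    subcommand command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    emmeans,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
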