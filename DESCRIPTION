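Package: kinbias
Title: Kin-Biased Association and Interaction Analysis for Fission-Fusion Societies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether fathers in promiscuous fission-fusion
    societies bias association and interaction toward their own offspring.
    Implements dyadic male by mother-infant association proportions with
    per-male z-standardization inside six-month infant-age windows,
    observed-versus-expected kin-category interaction statistics with
    one-sample sign-flip permutation tests, Elo-rating dominance ranks,
    Gaussian mixed models with within-bin Tukey-style contrasts, and a
    binomial mixed model linking early association to subsequent paternity.
    A configurable fission-fusion community simulator generates focal-follow
    and family-follow observation tables so that every stage of the pipeline
    can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
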