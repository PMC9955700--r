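Package: twinfam
Title: Twin-Family Similarity and Association Analysis for Binary Pain Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical twin-family design applied to binary
    questionnaire traits such as pediatric low back pain. Computes twin-pair
    similarity (casewise concordance, phi correlation on the double-entered
    table, and the within-pair odds ratio with Woolf intervals) with
    monozygotic-versus-dizygotic comparison tests; child-relative association
    by random twin selection, per-relative logistic regression and
    inverse-variance-weighted combination; univariate and multivariable
    association tables using family-clustered random-intercept logistic
    regression; and a liability-threshold ACE cohort simulator with
    closed-form bivariate-normal oracles for expected pair similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
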