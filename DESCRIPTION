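Package: mocgain
Title: Psychoacoustic Modeling and Analysis of Cochlear Gain Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cochlear gain reduction elicited by preceding
    sound (the medial olivocochlear reflex) with forward-masking
    psychophysics. Provides a mechanistic listener model built on two-segment
    cochlear input-output functions, power-spectrum-model threshold
    predictions under competing gain-reduction and additivity-of-masking
    hypotheses, Monte-Carlo simulation of 2-down/1-up adaptive tracking with
    an exact Markov-chain convergence oracle, equivalent-rectangular-bandwidth
    (ERB) level conversions for broadband elicitors, and the estimation
    pipeline: gain-reduction estimates, summary-statistic t-tests with
    Holm-Bonferroni correction, floor filtering, and linear mixed-effects
    models of gain-reduction growth with elicitor level, plus synthetic-cohort
    generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    knitr,
    rmarkdown
Config/testthat/edition: 3
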