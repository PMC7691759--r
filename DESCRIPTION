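Package: metgains
Title: Genetic Gain Estimation from Multi-Environment Yield Trial Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates annual genetic gain for grain yield from series of
    replicated multi-environment trials with recurring long-term checks, the
    era-trial design used by international wheat nurseries. Provides
    single-trial alpha-lattice mixed-model analysis by restricted maximum
    likelihood with repeatability-based trial filtering, exact one-dimensional
    k-means classification of trials into yield environments, a factor-analytic
    multi-environment mixed model for best linear unbiased prediction of line
    performance, check-relative yield expression and regression of the top
    decile of lines on trial year, and pedigree-based coefficient-of-parentage
    computation with principal-component grouping of the highest yielding
    lines. A synthetic-data module generates trial series and pedigrees with a
    known injected genetic trend so every stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
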