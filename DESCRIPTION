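Package: sibmort
Title: Adult Mortality Estimation from Sibling Survival Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating adult mortality (the probability 35q15)
    from sibling survival histories, including shortened summary histories
    of the kind collected by mobile phone surveys. Implements hot-deck
    imputation of sibling ages and death dates from a reference survey
    (partial and complete modes), post-stratification weighting by capped
    iterative proportional fitting, direct person-year estimation of
    age-specific mortality rates with jackknife confidence intervals,
    data-quality diagnostics (Myers' blended index, sibship summaries),
    and a sibship microsimulator for validating the full pipeline under
    controlled reporting errors and selection.
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
    withr
Config/testthat/edition: 3
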