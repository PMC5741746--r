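Package: occumix
Title: Occupancy and N-Mixture Models for Monitoring Elusive Snake Populations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Single-season site-occupancy and binomial N-mixture models for
    transect surveys of low-detectability species, with logit-link covariates
    and log-transect-length offsets, AICc/QAICc model selection with Akaike
    weights, parametric-bootstrap Pearson chi-square goodness-of-fit and
    overdispersion (c-hat) estimation, empirical-Bayes posterior abundance with
    bootstrap intervals for total abundance, and survey-design calculators:
    minimum surveys for confidence of species absence and a one-tailed
    two-period power analysis for occupancy declines under imperfect
    detection. Ships a transcribed transect-survey fixture from an insular
    grass snake (Natrix helvetica) monitoring study and a seeded synthetic-data
    generator emulating its design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
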