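Package: stochlife
Title: Individual Stochasticity in Life Histories from Matrix Population Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the variability among individuals implied by a matrix
    population model: the first four moments and derived statistics (mean,
    variance, CV, skewness, excess kurtosis) of longevity via absorbing Markov
    chains, of lifetime reproductive output via Markov chains with Poisson
    rewards, plus cohort generation time, a continuous parity measure, and age
    at maturity by conditional absorption. Includes database-style eligibility
    screening and a quartile-based outlier rule, assembly of a 16-outcome life
    history trait table, PCA of life-history axes, within/between-population
    variance decomposition with the intraclass correlation coefficient, a
    synthetic model generator, and an individual-based cohort simulator used as
    a brute-force oracle for every analytic moment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
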