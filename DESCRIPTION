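Package: healthyLongevity
Title: Stochastic Analysis of Healthy Longevity and DALYs via Markov
    Chains with Rewards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Matrix methods for the stochastic analysis of healthy
    longevity. The life course is described as an age- or stage-classified
    absorbing Markov chain; health outcomes (binary prevalences, grouped
    categorical or ordinal prevalences, or empirical moments of a
    quantitative measure such as grip strength) enter as per-transition
    "rewards". A general moment recursion yields the mean, variance,
    standard deviation, coefficient of variation, and skewness of
    remaining lifetime healthy longevity for every starting age class,
    a decomposition of variance within and among life-course
    trajectories, and the same statistics for disability-adjusted life
    years (years of life lost to mortality plus years lived with
    disability). Includes exhaustive-enumeration and Monte Carlo
    reference implementations, readers for life-table and prevalence
    files, and a synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
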