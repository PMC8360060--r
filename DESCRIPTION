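Package: flexbb
Title: Flexible Beta-Binomial Regression for Overdispersed Binomial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian regression for overdispersed binomial counts built on
    the flexible beta-binomial (FBB) distribution, a structured two-component
    mixture of beta-binomials with a common precision that preserves the
    intraclass-correlation interpretation while accommodating latent groups,
    excess zeros and outliers. Provides exact probability functions, moments
    and samplers for the beta-binomial, flexible beta-binomial and
    zero-inflated families; adaptive-Metropolis posterior sampling with
    convergence diagnostics; WAIC, conditional predictive ordinates and
    posterior predictive checks; and simulation-study harnesses for
    overdispersion, zero-excess and outlier-contamination designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    coda
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    readr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
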