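Package: quantfp
Title: Bayesian Fractional-Polynomial Quantile Regression with Variable Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric non-linear quantile regression using fractional-polynomial
    (FP) bases, with Bayesian variable selection under a quantile-specific Zellner
    g-prior. Implements the asymmetric-Laplace working likelihood and its
    normal-exponential scale mixture, a three-stage estimator (EM posterior modes,
    Gibbs sampling with generalised-inverse-Gaussian latents and importance
    reweighting, and stochastic search over model indicators yielding marginal
    inclusion probabilities), frequentist and unregularised Bayesian comparison
    fitters, MCMC diagnostics, descriptive-association statistics (Cramer's V with
    qualitative strength labels), and a seeded generator of NHANES-like blood
    pressure datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
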