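Package: ropemr
Title: Bayesian Mendelian Randomization with an Interval Causal Null
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian Mendelian randomization (MR) for individual-level data
    with an interval null hypothesis: causal-effect values inside a region of
    practical equivalence (ROPE) [-T, T] are treated as "no effect". The
    generative model couples a linear instrument-exposure stage with a
    logistic outcome stage and a latent confounder, and handles missing
    exposure values by sampling them jointly with the parameters. Posterior
    draws are obtained by blocked Markov chain Monte Carlo under a convenient
    continuous ("used") prior for the causal effect and converted to draws
    under the intended mixture ("true") prior by importance resampling. The
    posterior odds of the ROPE drive a ternary causal-discovery decision rule
    (accept the null / claim a discovery / uncertain), which can be calibrated
    against a frequentist inverse-variance-weighted (IVW) comparator through a
    loss-function-based simulation experiment. Includes a self-contained
    simulator for instrument, exposure and outcome data with controllable
    missingness, instrument strength and causal-effect size.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
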