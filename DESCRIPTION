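Package: normgaps
Title: Effects of Gender-Age-Imbalanced Sampling and Missing Covariates on
    Survey-Based Norm-Health Models
Version: 0.1.0
Authors@R:
    person("Survey", "Methods Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for quantifying how gender-age-imbalanced
    sampling and wholly missing covariates distort survey-weighted estimates of
    the association between community-level adult attitude-behaviour
    discordance (pre-marital sex norms) and adolescent HIV risk. Generates
    DHS-like multi-stage cluster survey microdata with a known log-linear risk
    model, resamples a balanced survey with replacement to match target
    gender-age marginal distributions with design-weight recalculation, fits
    survey-weighted modified-Poisson prevalence-ratio models with
    cluster-robust variance, runs bootstrap tests for effect-measure
    interaction, Wald tests for covariate-missingness scenarios, and
    inter-survey meta-analyses of when imbalance biases conclusions.
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
    withr,
    optparse
Config/testthat/edition: 3
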