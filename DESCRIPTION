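Package: tremortime
Title: Motor Tremor Effects on Duration Judgments via Cue Combination and
    Levy-Flight Diffusion Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for temporal bisection
    experiments in which mechanically induced motor tremor degrades the
    precision of auditory and visual duration judgments.  Implements
    inverse-variance (Bayesian) cue combination of sensory and motor
    duration estimates, a drift-diffusion model with symmetric alpha-stable
    (Levy-flight) momentary noise simulated by first-passage Euler
    integration, cumulative-Gumbel psychometric fitting with bisection-point
    and coefficient-of-variation extraction, quantile-probability
    chi-square estimation of diffusion parameters, repeated-measures ANOVA
    with linear contrasts and rank-based group comparisons, and a synthetic
    trial-table generator that reproduces the two-experiment design
    (7 log-spaced durations x 3 tremor amplitudes x 3 tremor frequencies).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
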