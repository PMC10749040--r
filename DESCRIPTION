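Package: racelatent
Title: Latent Natal-Sex Regression for Mass-Participation Race Times
Version: 0.1.0
Authors@R: person("Race", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing sex and gender-identity effects on
    mass-participation road-race finish times when natal sex is only
    partially observed. Provides probabilistic natal-sex imputation from
    US Social Security Administration baby-name frequencies, construction
    of a one-record-per-athlete cross-race dataset via trimmed no-intercept
    marathon calibration, linear models of log finish time containing a
    latent binary natal-sex covariate fitted by EM on the marginal
    likelihood, parametric-bootstrap Monte Carlo p-values, a two-sample
    power calculator, and a synthetic-data generator with known ground
    truth for recovery and calibration testing.
License: MIT
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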