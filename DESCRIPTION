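Package: eftdrk
Title: Exponentially Fitted Two-Derivative Runge-Kutta Methods for
    Oscillatory Genetic Regulatory Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fixed-step two-derivative Runge-Kutta (TDRK) integrators of
    algebraic order six whose update weights are exponentially fitted to a
    user-chosen frequency, designed for oscillatory ordinary differential
    equation models of gene regulation.  Provides the prototype TDRK4s6
    method and three exponentially fitted variants (EFTDRK4s6a/b/c), the
    two-gene cross-regulation benchmark and the five-variable Goldbeter
    model of PER circadian oscillations in Drosophila, steady-state and
    eigenvalue analysis, limit-cycle frequency estimation, global-error
    studies, best-fitting-frequency searches, and exact rational
    power-series verification of the sixth-order conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
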