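Package: frridge
Title: Fractional Ridge Regression
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ridge regression reparameterized by the fraction of the
    ordinary-least-squares coefficient L2-norm that the regularized
    solution should retain. Given a design matrix, many target vectors
    and requested fractions in [0, 1], the solver returns coefficients
    whose norms are the requested fractions of the unregularized
    (pseudoinverse) solution's norm, together with the per-target ridge
    penalties alpha that achieve each fraction. Includes closed-form
    identities (flat-spectrum solutions, effective degrees of freedom),
    an estimator-style fit/predict/score layer with cross-validated
    fraction selection, a synthetic-scenario simulation harness with
    standard-ridge baselines, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: MASS, stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
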