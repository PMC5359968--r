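Package: monomed
Title: Adaptive Monotonic Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mediation analysis for positive continuous predictors,
    mediators, and outcomes under monotonic (fractional-polynomial,
    degree-1) relationships.  Outcome, mediator, and predictor enter
    through single power transforms whose exponents are selected by
    (power-adjusted) likelihood cross-validation; the two mediation
    regressions are estimated jointly as a bivariate-normal composite
    model with optional log-linear variance models and a single
    cross-stream correlation.  Provides instantaneous natural direct,
    indirect, and total effect curves, bias-corrected bootstrap
    confidence intervals for the instantaneous indirect effect with a
    normalized-width summary, moderated mediation for discrete
    moderators, and simulation generators for method evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
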