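Package: sinetrend
Title: Nonlinear Model-Based Analysis of Time-Course Gene Expression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models time-course gene expression profiles as a damped
    sinusoid plus a linear trend, x(t) = exp(alpha*t)*(a*cos(omega*t) +
    b*sin(omega*t)) + c*t + d. Provides a fast two-step linear
    least-squares estimator of all six parameters via a second-order ODE
    reformulation, an F-test that screens model-following (e.g.
    periodically expressed) genes from white noise, a model-based
    relocation-iteration clustering algorithm with random or k-means
    initialisation and multiple restarts, synthetic-data generators for
    benchmarking, and evaluation metrics (sensitivity/specificity
    threshold sweeps, adjusted Rand index, AARI).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
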