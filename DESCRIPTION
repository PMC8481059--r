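Package: eiwss
Title: Stress-Strength Reliability for the Exponentiated Inverted Weibull
    Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the stress-strength reliability R = P(Y < X) when
    strength and stress follow exponentiated inverted Weibull distributions
    sharing a common shape parameter.  Provides the distribution primitives,
    eight frequentist estimators of (theta1, theta2, beta) and R (maximum
    likelihood via profile-likelihood root finding, maximum product of
    spacings, minimum spacing absolute and absolute-log distance, least
    squares, weighted least squares, Cramer-von Mises, and Anderson-Darling),
    parametric bootstrap percentile and bias-corrected percentile confidence
    intervals for R, Kolmogorov-Smirnov goodness-of-fit support, a Monte Carlo
    simulation harness for comparing the estimators by mean, mean squared
    error and interval length, and the jute-fiber and carbon-fiber
    breaking-strength case-study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    readr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
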