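Package: refrange
Title: Reference Ranges as Prediction and Tolerance Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs clinical reference ranges for a quantitative marker as
    parametric (normal-theory) and nonparametric (order-statistic) prediction
    and tolerance intervals, and quantifies -- exactly by quadrature and by
    Monte Carlo simulation -- the probability that each candidate interval
    actually contains the intended proportion of the population.  Implements
    the closed-form interval multipliers for normal samples, exact two-sided
    and equal-tailed tolerance factors solved from their defining coverage
    probabilities, the beta-distribution coverage confidence of
    distribution-free intervals, minimum sample sizes for distribution-free
    tolerance intervals, and diagnostics for the distribution of the random
    content of a data-based interval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
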