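---
title: "Reference ranges: prediction intervals, tolerance intervals, and the coverage they actually deliver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference ranges: prediction intervals, tolerance intervals, and the coverage they actually deliver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refrange)
```

## The problem

A clinical laboratory reports a *reference range* alongside a patient's
measurement of a quantitative marker (plasma glucose, serum creatinine,
TSH, ...): an interval meant to contain a large proportion $P$ (usually
95%) of the values in a healthy reference population, so that a value
falling outside it is flagged as atypical.

The range is estimated from a random sample $X_1, \dots, X_n$ from the
population. Because the sample is random, the proportion of the population
a data-based interval actually contains — its *content* $K$ — is itself a
random variable. The central question this package addresses is therefore
not only "what is the interval?" but "with what probability does the
interval contain at least $100P\%$ of the population?".

## Normal-theory intervals

Assume the marker is $N(\mu, \sigma^2)$ with both parameters unknown, and
write $\bar X$ and $S$ for the sample mean and the $(n-1)$-denominator
standard deviation. All intervals considered have the form
$\bar X \pm c\,S$; the choice of the multiplier $c$ is everything.

* **Prediction interval (RR1).**
  $c_1 = t_{(1+P)/2,\,n-1}\sqrt{1 + 1/n}$. It covers one future
  observation with probability exactly $P$, equivalently its content
  satisfies $E(K) = P$.
* **Percentile plug-in estimators (RR2–RR4).** $c_2 = z_{(1+P)/2}$ (naive
  plug-in), $c_3 = c_2 / \lambda_\nu$ (minimum-variance unbiased estimation
  of the percentiles) and $c_4 = c_2 \lambda_\nu$ (minimum mean squared
  error), where
  $\lambda_\nu = \sqrt{2/\nu}\,\Gamma((\nu+1)/2)/\Gamma(\nu/2)$ is the
  expectation of $S/\sigma$. `lambda_nu()` evaluates this via log-gamma
  differences; the direct gamma ratio overflows around $\nu \approx 170$.
* **Two-sided tolerance interval (RR5).** $c_5$ solves
  $\Pr\{K \ge P\} = \gamma$, where, writing
  $Z = \sqrt{n}(\bar X - \mu)/\sigma \sim N(0,1)$ independent of
  $\chi^2_\nu = \nu S^2/\sigma^2$,
  $$K = \Phi\!\Big(\tfrac{Z}{\sqrt n} + c\sqrt{\tfrac{\chi^2_\nu}{\nu}}\Big)
        - \Phi\!\Big(\tfrac{Z}{\sqrt n} - c\sqrt{\tfrac{\chi^2_\nu}{\nu}}\Big).$$
* **Equal-tailed (central) tolerance interval (RR6).** $c_6$ solves
  $\Pr\{\bar X - c S < \mu - z_{(1+P)/2}\sigma
  \text{ and } \mu + z_{(1+P)/2}\sigma < \bar X + c S\} = \gamma$:
  the interval must contain the *central* $100P\%$ band of the population,
  a strictly stronger requirement, so $c_6 > c_5$ always.

### Why the prediction interval fails as a reference range

$E(K) = P$ is an average over laboratories, not a guarantee for the one
sample at hand. The package computes $\Pr\{K < P\}$ exactly; for the
prediction multiplier this under-coverage probability is already 0.385 at
$n = 20$, climbs with $n$, and tends to $1/2$: with a large sample, a lab
using the prediction interval has roughly a coin-flip chance of reporting
a range that contains less than $100P\%$ of its population. The tolerance
interval pins this probability at $1 - \gamma$ by construction.

```{r undercoverage}
asymptotic_check(c(20, 50, 100, 150), content = 0.95)
```

## Numerical choices

* **Coverage probabilities by deterministic quadrature.** Both defining
  probabilities are even in $Z$, so they are evaluated as
  $2\int_0^8 \phi(z)\,\Pr\{\chi^2_\nu \ge \nu\,w^*(z)^2\}\,dz$ on a fixed
  96-node Gauss–Legendre rule. Truncating at $z = 8$ discards less than
  $10^{-15}$ of normal mass; the quadrature error is far below the
  $10^{-6}$ the factor solvers rely on. For the two-sided probability the
  threshold $w^*(z)$ — the smallest $S/\sigma$ ratio at which the content
  reaches $P$ — is found per node by monotone root-finding (the content is
  strictly increasing in $w$, from 0 to 1, so the root always exists); for
  the equal-tailed probability the threshold is available in closed form.
* **Factor solvers.** `two_sided_factor()` and `equal_tailed_factor()`
  root-solve their coverage probability against $\gamma$ with Brent's
  method on the bracket $[z_{(1+P)/2},\ 10\,z_{(1+P)/2}]$ (expanded if
  needed), absolute tolerance $10^{-9}$ on $c$. Both probabilities are
  smooth and strictly increasing in $c$, so a derivative-free bracketed
  solver is robust. Each result carries its re-evaluated achieved
  confidence and residual.
* **Content simulation.** `simulate_content()` draws $(Z, \chi^2_\nu)$
  directly rather than whole samples, so $10^6$ replicates cost three
  vectorised draws. Every simulation entry point takes an explicit seed,
  seeds a local RNG state, and restores the caller's state — identical
  seeds give bitwise-identical draws, and no function touches global RNG
  state as a side effect.
* **Skewness and kurtosis** of simulated contents use the plain
  moment-based sample definitions, with kurtosis reported as excess.
  The kernel density option in `summarize_content()` uses a Gaussian
  kernel with Silverman's plug-in bandwidth on a 512-point grid; bandwidth
  is a presentation choice, so the density is qualitative output only.
* **Reporting precision.** All computation is in full double precision;
  only the reporting layer rounds (default 2 decimals, configurable via
  `analysis_config(decimals = )`).

## Distribution-free intervals

Without a normality assumption, intervals are formed from order statistics
$(X_{[j]}, X_{[n-j+1]})$. For any continuous population the content of the
depth-$j$ interval has the $\mathrm{Beta}(n - 2j + 1,\ 2j)$ distribution
(Tukey's equivalence-blocks argument), which gives everything in closed
form:

* `j_prediction()`: the prediction depth
  $j^{(p)} = \lfloor (n+1)(1-P)/2 \rfloor$, whose interval has expected
  content $\ge P$;
* `coverage_confidence_np()`: the coverage confidence
  $1 - B_{n-2j+1,\,2j}(P)$ of any depth;
* `j_tolerance()`: the largest depth whose confidence reaches $\gamma$,
  by direct search over $1 \le j \le \lfloor n/2 \rfloor$;
* `minimum_n()`: the smallest $n$ for which even the extreme-value
  interval $(X_{[1]}, X_{[n]})$ qualifies, i.e.
  $1 - (nP^{n-1} - (n-1)P^n) \ge \gamma$, with powers of $P$ evaluated in
  log space. At $(P, \gamma) = (0.95, 0.95)$ this gives the classical
  $n = 93$.

Two small numerical guards are worth recording. The depth formula adds
$10^{-9}$ before taking the floor: at, e.g., $n = 19$, $P = 0.9$ the
product $(n+1)(1-P)/2$ is exactly 1 in real arithmetic but
$0.9999\ldots98$ in doubles, and without the guard the depth would
collapse to 0. Similarly the `minimum_n()` comparison uses a $10^{-12}$
tolerance: at $(P, \gamma) = (0.5, 0.5)$ the $n = 3$ criterion equals
$1/2$ exactly but evaluates just below it in log-space doubles.

**Ties.** The coverage theory assumes a continuous population, but real
laboratory values are rounded. `extract_interval()` permits ties (depths
are counted through duplicates by stable sorting) and warns when more than
1% of values are tied, since the beta coverage statement then holds only
approximately. Interval endpoints are reported as the open interval
$(X_{[j]}, X_{[n-j+1]})$; under continuity open versus closed is
immaterial, and the convention is recorded on the object.

**Infeasibility is actionable.** When no depth achieves $\gamma$ (or no
interior prediction depth exists), the error message carries the minimum
sample size required, so a user planning a reference-interval study learns
what $n$ to aim for.

## The synthetic-data generator

`generate_fixture()` supplies the study conditions for tests and examples:

* `normal` with `exact_moments = TRUE` rescales the draw affinely so the
  sample mean and SD match the targets *exactly*. This reproduces the
  worked example of a glucose sample with $n = 210$, $\bar X = 5.31$,
  $S = 0.41$ mmol/L: all normal-theory intervals depend on the data only
  through $(n, \bar X, S)$, so the fixture makes them reproducible
  bit-for-bit from published summary statistics alone.
* `lognormal` is parameterised to the target mean and SD and is
  right-skewed, as many enzyme and hormone markers are.
* `mixture` is a contaminated normal,
  $0.9\,N(\mu, \sigma^2) + 0.1\,N(\mu, 9\sigma^2)$: symmetric but
  heavy-tailed, the classic stress test for normal-theory intervals.

What the generator does *not* emulate: rounding/quantisation of real
laboratory instruments (beyond the tie warning above), age- or
sex-structured mixtures, analytical drift between batches, or outliers
from sample handling. Passing tests on these fixtures therefore validate
the probability computations, not the fitness of any parametric assumption
for a particular real marker — checking normality on real data remains the
user's responsibility and is out of scope here.

## Problem sizes used in the test suite

The distributional claims are verified with $10^6$ simulated contents
where a published simulation is being reproduced (matching its replicate
count, Monte-Carlo standard error $\approx 5\times10^{-4}$), and with
$2\times10^5$ replicates for the quadrature-versus-simulation
cross-checks, which bounds each check at three Monte-Carlo standard
errors. Factor-ordering properties are scanned over every
$n \in \{2, \dots, 150\}$; asymptotic statements are checked at
$n = 10^5$.

## Worked example

```{r example}
s <- sample_summary(n = 210, mean = 5.31, sd = 0.41)
run_analysis(s, analysis_config(methods = c("RR1", "RR5", "RR6")))
```

The equal-tailed factor is also an exact two-sided tolerance factor at a
higher content level:

```{r content-for-factor}
c6 <- equal_tailed_factor(210, range_spec(0.95, 0.95))$factor
content_for_factor(c6, n = 210, confidence = 0.95)
```

and with raw data the distribution-free ranges join the report:

```{r nonparametric}
x <- generate_fixture(210, 5.31, 0.41, seed = 1, exact_moments = TRUE)
run_analysis(x, analysis_config(methods = c("RR7", "RR8")))
```

(The order-statistic endpoints above come from the synthetic fixture; with
a laboratory's own measurements, `read_values()` loads them from CSV/TSV
and the depths $j^{(p)} = 5$, $j^{(t)} = 3$ at $n = 210$ are data-free.)

## Known limitations

* One-sided reference limits, Bayesian intervals, tolerance regions for
  multivariate markers, and regression tolerance bands are not
  implemented.
* Equal-tailed *distribution-free* tolerance intervals are not provided;
  only the plain (P, γ) version is.
* No normality testing is bundled; pair with `shapiro.test()` or the
  `nortest` package before trusting the normal-theory methods.
* Reference-range partitioning (age/sex strata) and sample-size planning
  beyond `minimum_n()` are out of scope.
* The exact quadrature assumes the normal model holds; under the skewed or
  heavy-tailed fixture families only the distribution-free methods retain
  their stated coverage.
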