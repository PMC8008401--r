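# refrange

Reference ranges for clinical laboratory markers, with honest coverage.

A reference range is a data-based interval meant to contain a large
proportion *P* (typically 95%) of a healthy population's values for a
quantitative marker; a patient's value outside it is flagged as atypical.
Because the range is estimated from a random sample, the proportion it
*actually* contains — its content *K* — is random. `refrange` constructs
the standard candidate intervals and, crucially, quantifies
`Pr{K >= P}` for each of them, exactly (by quadrature or beta
distributions) and by simulation.

## Methods

For a normal sample with mean `X̄` and SD `S`, all intervals have the form
`X̄ ± c·S`:

| method | multiplier | property |
|---|---|---|
| RR1 | `c1 = t_{(1+P)/2,n-1}·sqrt(1+1/n)` | *P* prediction interval: `E(K) = P` |
| RR2–RR4 | `z_{(1+P)/2}`, `z/λ_ν`, `z·λ_ν` | percentile plug-in estimators |
| RR5 | `c5` solves `Pr{K ≥ P} = γ` | two-sided (P, γ) tolerance interval |
| RR6 | `c6` solves central-band containment = γ | equal-tailed tolerance interval |

Distribution-free analogues use order statistics `(X_[j], X_[n−j+1])`,
whose content is `Beta(n−2j+1, 2j)`-distributed for any continuous
population: RR7 (prediction depth `j = ⌊(n+1)(1−P)/2⌋`) and RR8 (tolerance
depth, the largest `j` with `1 − pbeta(P, n−2j+1, 2j) ≥ γ`), plus the
minimum sample size at which RR8 exists (`minimum_n(0.95, 0.95)` is 93).

The central message the diagnostics carry: a *P* prediction interval
under-covers (`K < P`) with probability approaching 1/2 as *n* grows —
at `n = 150` it is already 0.459 — so it is unsuitable as a reference
range; a (P, γ) tolerance interval caps that probability at `1 − γ` by
construction.

## Worked example

Fasting plasma glucose, `n = 210`, `X̄ = 5.31`, `S = 0.41` mmol/L — summary
statistics are all the normal-theory methods need:

```r
library(refrange)
s <- sample_summary(210, 5.31, 0.41)
run_analysis(s, analysis_config(methods = c("RR1", "RR5", "RR6")))
```

```
Reference range analysis (summary(n=210, mean=5.31, sd=0.41); P = 0.95, gamma = 0.95)
  RR1 = [4.50, 6.12]  (c = 1.98)
      with probability 47% this interval contains less than 95% of the population
  RR5 = [4.43, 6.19]  (c = 2.14)
      contains >= 95% of the population with probability 95%
      contains the central 95% band with probability 86%
  RR6 = [4.40, 6.22]  (c = 2.21)
      contains >= 95% of the population with probability 99%
      contains the central 95% band with probability 95%
      guarantees 95.7% content at confidence 95%
```

Reading: the prediction interval RR1 is the narrowest but fails its stated
goal 47% of the time; the tolerance interval RR5 guarantees 95% content
with 95% confidence; the equal-tailed RR6 additionally contains the
central 95% band of the population with 95% probability, and as a plain
tolerance interval it actually guarantees 95.7% content.

With raw values (here a synthetic sample standardised to the same
moments), the distribution-free ranges join in:

```r
x <- generate_fixture(210, 5.31, 0.41, seed = 1, exact_moments = TRUE)
run_analysis(x, analysis_config(methods = c("RR7", "RR8")))
```

```
  RR7 = [4.51, 6.22]  (depth j = 5)
      with probability 39% this interval contains less than 95% of the population
  RR8 = [4.43, 6.28]  (depth j = 3)
      contains >= 95% of the population with probability 95%
```

A thin command-line front end wraps the same functions:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "refrange.R", package = "refrange"))')
Rscript "$cli" range --n 210 --mean 5.31 --sd 0.41 --method RR1,RR5,RR6
Rscript "$cli" diagnose --n 210
Rscript "$cli" curves --kind undercoverage --nmin 20 --nmax 150 --file curves.tsv
Rscript "$cli" fixture --n 210 --mean 5.31 --sd 0.41 --exact --file glucose.csv
```

See `vignettes/reference-intervals.Rmd` for the model, the quadrature and
solver details, and the limitations.

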