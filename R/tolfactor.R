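# Exact normal-theory tolerance factors.
#
# Both coverage probabilities below are expectations over (Z, chi^2_nu) with
# Z ~ N(0,1) independent of chi^2_nu.  They are evaluated by fixed-node
# Gauss-Legendre quadrature over z in [0, 8] (the integrands are even in z);
# the mass of N(0,1) beyond 8 is < 1e-15, far below the 1e-6 accuracy the
# solvers rely on.

.quad_cache <- new.env(parent = emptyenv())

gauss_nodes <- function(n_nodes = 96L, a = 0, b = 8) {
  key <- paste(n_nodes, a, b, sep = "_")
  if (is.null(.quad_cache[[key]])) {
    .quad_cache[[key]] <- pracma::gaussLegendre(n_nodes, a, b)
  }
  .quad_cache[[key]]
}

#' Content of the interval mean +/- c * sd at given sample deviates
#'
#' For a normal population, the proportion of the population contained in
#' `Xbar +/- c * S` depends on the sample only through the standardized mean
#' deviate `Z = sqrt(n) (Xbar - mu) / sigma` and the standard-deviation ratio
#' `W = S / sigma`.  This function returns that proportion,
#' `Phi(z / sqrt(n) + c w) - Phi(z / sqrt(n) - c w)`, for fixed `(z, w)`.
#' It is the integrand of every coverage probability in this package.
#'
#' @param z standardized mean deviate (any real).
#' @param w ratio of sample to population standard deviation, `w >= 0`.
#' @param c interval multiplier, `c > 0`.
#' @param n sample size, at least 2.
#' @return The contained population proportion, in `[0, 1)`.
#' @examples
#' content_of(0, 1, 1.96, 210)  # close to 2 * pnorm(1.96) - 1
#' @export
content_of <- function(z, w, c, n) {
  stopifnot(all(w >= 0), c > 0, n >= 2)
  stats::pnorm(z / sqrt(n) + c * w) - stats::pnorm(z / sqrt(n) - c * w)
}

# w such that content_of(z, w, c, n) == P; content is strictly increasing in
# w from 0 to 1, so the root exists and is unique for every z.
content_root_w <- function(z, c, n, content) {
  stats::uniroot(function(w) content_of(z, w, c, n) - content,
                 lower = 1e-12, upper = 10, extendInt = "upX",
                 tol = 1e-12)$root
}

#' Coverage confidence of a two-sided normal interval
#'
#' The probability, over repeated sampling, that the interval
#' `Xbar +/- c * S` contains at least a proportion `content` of a normal
#' population.  Computed by deterministic quadrature: for each node `z` the
#' threshold standard-deviation ratio `w*(z)` with content exactly `content`
#' is found by monotone root-finding, and the chi-square tail probability
#' `Pr{chi^2_nu >= nu w*(z)^2}` is accumulated against the standard normal
#' density, exploiting symmetry in `z`.  Absolute accuracy is well below
#' 1e-6.
#'
#' @param c interval multiplier, `c > 0`.
#' @param n sample size, at least 2.
#' @param content content level P in (0, 1).
#' @return A probability: `Pr{content of the interval >= P}`.
#' @examples
#' c1 <- rr_factor("c1", 210, 0.95)
#' coverage_confidence(c1, 210, 0.95)  # about 0.53: RR1 under-covers often
#' @export
coverage_confidence <- function(c, n, content) {
  stopifnot(c > 0, n >= 2, content > 0, content < 1)
  nu <- n - 1
  gl <- gauss_nodes()
  vals <- vapply(gl$x, function(z) {
    w <- content_root_w(z, c, n, content)
    stats::dnorm(z) * stats::pchisq(nu * w^2, nu, lower.tail = FALSE)
  }, numeric(1))
  min(1, 2 * sum(gl$w * vals))
}

#' Central containment probability of a two-sided normal interval
#'
#' The probability that `Xbar +/- c * S` contains the *central* population
#' band `mu +/- z_{(1+P)/2} sigma`, i.e. that both
#' `Xbar - c S < mu - z_{(1+P)/2} sigma` and
#' `mu + z_{(1+P)/2} sigma < Xbar + c S` hold.  Equivalently
#' `Pr{c (S/sigma) >= z_{(1+P)/2} + |Z| / sqrt(n)}`, evaluated by a single
#' half-line quadrature.  Containing the central band implies content at
#' least P, so this probability never exceeds [coverage_confidence()] at the
#' same `c`.
#'
#' @inheritParams coverage_confidence
#' @return A probability.
#' @examples
#' central_coverage_confidence(2.14, 210, 0.95)
#' @export
central_coverage_confidence <- function(c, n, content) {
  stopifnot(c > 0, n >= 2, content > 0, content < 1)
  nu <- n - 1
  zp <- stats::qnorm((1 + content) / 2)
  gl <- gauss_nodes()
  vals <- stats::dnorm(gl$x) *
    stats::pchisq(nu * ((zp + gl$x / sqrt(n)) / c)^2, nu, lower.tail = FALSE)
  min(1, 2 * sum(gl$w * vals))
}

# shared root-solve in c with bracket expansion; f is increasing in c
solve_factor_for <- function(f, n, content, confidence) {
  lower <- stats::qnorm((1 + content) / 2)
  upper <- 10 * lower
  while (f(upper) < confidence && upper < 1e4) upper <- 2 * upper
  if (f(upper) < confidence) {
    stop("solver failure: could not bracket the tolerance factor",
         call. = FALSE)
  }
  stats::uniroot(function(c) f(c) - confidence, lower = lower, upper = upper,
                 tol = 1e-9)$root
}

#' Exact two-sided (P, gamma) tolerance factor
#'
#' Solves for the multiplier `c` such that the interval `Xbar +/- c * S`
#' contains at least a proportion P of the normal population with probability
#' exactly gamma over the randomness of the sample -- the defining property
#' of a two-sided tolerance interval.  The root of
#' `coverage_confidence(c, n, P) = gamma` is found by bracketed
#' root-finding starting from `[z_{(1+P)/2}, 10 z_{(1+P)/2}]`.
#'
#' @param n sample size, at least 2.
#' @param spec a [range_spec()] giving P and gamma.
#' @return A `factor_result`: the solved `factor`, its `achieved_confidence`
#'   (re-evaluated at the root), the targets, and the solver `residual`.
#' @examples
#' two_sided_factor(210, range_spec(0.95, 0.95))  # factor about 2.14
#' @export
two_sided_factor <- function(n, spec = range_spec()) {
  stopifnot(n >= 2, inherits(spec, "range_spec"))
  root <- solve_factor_for(function(c) coverage_confidence(c, n, spec$content),
                           n, spec$content, spec$confidence)
  achieved <- coverage_confidence(root, n, spec$content)
  new_factor_result(root, achieved, spec, n, method = "two_sided")
}

#' Exact equal-tailed (central) tolerance factor
#'
#' Solves for the multiplier `c` such that `Xbar +/- c * S` contains the
#' central band `mu +/- z_{(1+P)/2} sigma` of the normal population with
#' probability gamma.  Because central containment is a stronger requirement
#' than content >= P, this factor always exceeds the plain two-sided factor
#' at the same `(n, P, gamma)`.
#'
#' @inheritParams two_sided_factor
#' @return A `factor_result` with `method = "equal_tailed"`.
#' @examples
#' equal_tailed_factor(210, range_spec(0.95, 0.95))  # factor about 2.21
#' @export
equal_tailed_factor <- function(n, spec = range_spec()) {
  stopifnot(n >= 2, inherits(spec, "range_spec"))
  root <- solve_factor_for(
    function(c) central_coverage_confidence(c, n, spec$content),
    n, spec$content, spec$confidence)
  achieved <- central_coverage_confidence(root, n, spec$content)
  new_factor_result(root, achieved, spec, n, method = "equal_tailed")
}

#' Content level achieved by a given factor at fixed confidence
#'
#' Inverts the coverage-confidence relation in P: given a multiplier `c`,
#' finds the content level P such that `Xbar +/- c * S` is an exact
#' (P, gamma) tolerance interval.  Used, for instance, to ask what content
#' the wider equal-tailed factor actually guarantees at the same confidence.
#'
#' @param c interval multiplier, `c > 0`.
#' @param n sample size, at least 2.
#' @param confidence confidence level gamma in (0, 1).
#' @return The content level P in (0, 1).
#' @examples
#' c6 <- equal_tailed_factor(210, range_spec(0.95, 0.95))$factor
#' content_for_factor(c6, 210, 0.95)  # about 0.957
#' @export
content_for_factor <- function(c, n, confidence) {
  stopifnot(c > 0, n >= 2, confidence > 0, confidence < 1)
  lo <- 1e-6
  if (coverage_confidence(c, n, lo) < confidence) {
    stop("factor too small: no content level is guaranteed at confidence ",
         confidence, call. = FALSE)
  }
  # coverage_confidence is decreasing in P at fixed c
  stats::uniroot(function(p) coverage_confidence(c, n, p) - confidence,
                 lower = lo, upper = 1 - 1e-9, tol = 1e-7)$root
}

new_factor_result <- function(factor, achieved, spec, n, method) {
  structure(list(factor = factor,
                 achieved_confidence = achieved,
                 content = spec$content,
                 confidence_target = spec$confidence,
                 n = as.integer(n),
                 residual = abs(achieved - spec$confidence),
                 method = method),
            class = "factor_result")
}

#' @export
print.factor_result <- function(x, ...) {
  lab <- if (x$method == "two_sided") "Two-sided" else "Equal-tailed"
  cat(sprintf(
    "%s tolerance factor: c = %.4f  (n = %d, P = %g, gamma = %g; residual %.1e)\n",
    lab, x$factor, x$n, x$content, x$confidence_target, x$residual))
  invisible(x)
}
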