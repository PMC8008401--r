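#' Summarise a sample of marker values
#'
#' Computes the sufficient statistics of a normal sample: the sample size,
#' the arithmetic mean and the (n-1)-denominator standard deviation.  All
#' normal-theory reference ranges of the form `mean +/- c * sd` depend on the
#' data only through these three numbers, so a `sample_summary` can also be
#' built directly from published values with [sample_summary()].
#'
#' @param values numeric vector of at least two finite measurements.
#' @return A `sample_summary` object: a list with components `n`, `mean`,
#'   `sd` and `df` (degrees of freedom, `n - 1`).
#' @examples
#' summarize_sample(c(0, 0, 3, 3))
#' @seealso [sample_summary()] to enter printed summary statistics directly.
#' @export
summarize_sample <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop("'values' must be finite; found ", sum(!is.finite(values)),
         " non-finite entries", call. = FALSE)
  }
  if (length(values) < 2L) {
    stop("insufficient data: at least 2 observations are required",
         call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("degenerate sample: all values are equal (zero variance)",
         call. = FALSE)
  }
  sample_summary(n = length(values), mean = mean(values), sd = s)
}

#' Construct a sample summary from printed statistics
#'
#' @param n integer sample size, at least 2.
#' @param mean sample mean, in the units of the marker.
#' @param sd sample standard deviation (with `n - 1` in the denominator),
#'   strictly positive, same units.
#' @return A `sample_summary` object.
#' @examples
#' # fasting plasma glucose, n = 210, in mmol/L
#' sample_summary(210, 5.31, 0.41)
#' @export
sample_summary <- function(n, mean, sd) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, length(mean) == 1L, length(sd) == 1L)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2", call. = FALSE)
  if (!is.finite(mean)) stop("'mean' must be finite", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("'sd' must be > 0", call. = FALSE)
  structure(list(n = n, mean = as.numeric(mean), sd = as.numeric(sd),
                 df = n - 1L),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("Sample summary: n = %d, mean = %g, sd = %g (df = %d)\n",
              x$n, x$mean, x$sd, x$df))
  invisible(x)
}

#' Specify the target content and confidence of a reference range
#'
#' A reference range aims to contain a proportion `content` (P) of the
#' population; for tolerance intervals this must hold with probability
#' `confidence` (gamma) over the randomness of the sample.
#'
#' @param content target content level P, in (0, 1).  Default 0.95.
#' @param confidence confidence level gamma, in (0, 1).  Default 0.95.
#' @return A `range_spec` object.
#' @examples
#' range_spec(0.95, 0.95)
#' @export
range_spec <- function(content = 0.95, confidence = 0.95) {
  stopifnot(length(content) == 1L, length(confidence) == 1L)
  if (!is.finite(content) || content <= 0 || content >= 1) {
    stop("'content' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(confidence) || confidence <= 0 || confidence >= 1) {
    stop("'confidence' must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(content = content, confidence = confidence),
            class = "range_spec")
}

#' @export
print.range_spec <- function(x, ...) {
  cat(sprintf("Range spec: content P = %g, confidence gamma = %g\n",
              x$content, x$confidence))
  invisible(x)
}

#' Unbiasing constant for the sample standard deviation
#'
#' Computes `lambda_nu = sqrt(2/nu) * Gamma((nu+1)/2) / Gamma(nu/2)`, the
#' factor by which the expectation of S falls short of sigma in a normal
#' sample with `nu` degrees of freedom.  It enters the minimum-variance
#' unbiased (c3) and minimum-MSE (c4) percentile estimators.  Evaluated via
#' log-gamma differences so it remains finite for large `nu` (a direct gamma
#' ratio overflows near nu = 170).
#'
#' @param df degrees of freedom nu >= 1.
#' @return A number in (0, 1), tending to 1 as `df` grows.
#' @examples
#' lambda_nu(1)   # sqrt(2/pi)
#' lambda_nu(209)
#' @export
lambda_nu <- function(df) {
  if (any(!is.finite(df)) || any(df < 1)) {
    stop("'df' must be >= 1", call. = FALSE)
  }
  sqrt(2 / df) * exp(lgamma((df + 1) / 2) - lgamma(df / 2))
}

#' Closed-form normal-theory interval multipliers
#'
#' The four classical multipliers `c` in the reference range `mean +/- c * sd`
#' for a normal sample:
#' \describe{
#'   \item{`c1`}{`t_{(1+P)/2, n-1} * sqrt(1 + 1/n)` -- the P prediction
#'     interval for one future observation (RR1).}
#'   \item{`c2`}{`z_{(1+P)/2}` -- the naive plug-in percentile estimator
#'     (RR2).}
#'   \item{`c3`}{`c2 / lambda_nu` -- minimum-variance unbiased estimation of
#'     the population percentiles (RR3).}
#'   \item{`c4`}{`c2 * lambda_nu` -- minimum mean squared error among
#'     estimators `mean + c * sd` (RR4).}
#' }
#' `c1` is the largest of the four at every `n`, and decreases to
#' `z_{(1+P)/2}` as `n` grows.
#'
#' @param method one of `"c1"`, `"c2"`, `"c3"`, `"c4"`.
#' @param n sample size, at least 2.
#' @param content content level P in (0, 1).
#' @return The multiplier, a positive dimensionless number.
#' @examples
#' rr_factor("c1", n = 210, content = 0.95)  # about 1.97
#' rr_factor("c2", n = 210, content = 0.95)  # qnorm(0.975), n-free
#' @export
rr_factor <- function(method = c("c1", "c2", "c3", "c4"), n, content) {
  method <- match.arg(method)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2", call. = FALSE)
  if (content <= 0 || content >= 1) {
    stop("'content' must lie strictly between 0 and 1", call. = FALSE)
  }
  nu <- n - 1L
  z <- stats::qnorm((1 + content) / 2)
  switch(method,
         c1 = stats::qt((1 + content) / 2, df = nu) * sqrt(1 + 1 / n),
         c2 = z,
         c3 = z / lambda_nu(nu),
         c4 = z * lambda_nu(nu))
}

#' Build a normal-theory reference range
#'
#' Assembles the interval `mean +/- c * sd` where `c` is chosen by `method`:
#' RR1-RR4 use the closed-form multipliers of [rr_factor()], RR5 the exact
#' two-sided (P, gamma) tolerance factor of [two_sided_factor()], and RR6 the
#' equal-tailed (central) tolerance factor of [equal_tailed_factor()].
#' Distribution-free ranges (RR7, RR8) need the raw data and are built with
#' [extract_interval()] instead.
#'
#' @param method one of `"RR1"` ... `"RR6"`.
#' @param summary a [sample_summary()].
#' @param spec a [range_spec()]; `confidence` is used only by RR5 and RR6.
#' @return A `reference_range` object with components `lower`, `upper`,
#'   `factor`, `method`, `spec` and `n`.
#' @examples
#' s <- sample_summary(210, 5.31, 0.41)
#' build_range("RR1", s, range_spec(0.95, 0.95))
#' @export
build_range <- function(method = c("RR1", "RR2", "RR3", "RR4", "RR5", "RR6"),
                        summary, spec = range_spec()) {
  method <- match.arg(method)
  stopifnot(inherits(summary, "sample_summary"), inherits(spec, "range_spec"))
  c_mult <- switch(method,
    RR1 = rr_factor("c1", summary$n, spec$content),
    RR2 = rr_factor("c2", summary$n, spec$content),
    RR3 = rr_factor("c3", summary$n, spec$content),
    RR4 = rr_factor("c4", summary$n, spec$content),
    RR5 = two_sided_factor(summary$n, spec)$factor,
    RR6 = equal_tailed_factor(summary$n, spec)$factor)
  new_reference_range(lower = summary$mean - c_mult * summary$sd,
                      upper = summary$mean + c_mult * summary$sd,
                      factor = c_mult, method = method,
                      spec = spec, n = summary$n)
}

# internal constructor shared by parametric and order-statistic ranges
new_reference_range <- function(lower, upper, factor, method, spec, n,
                                indices = NULL) {
  stopifnot(lower < upper)
  structure(list(lower = lower, upper = upper, factor = factor,
                 method = method, spec = spec, n = n, indices = indices),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, digits = 2, ...) {
  cat(sprintf("%s reference range: [%s, %s]", x$method,
              formatC(x$lower, format = "f", digits = digits),
              formatC(x$upper, format = "f", digits = digits)))
  if (!is.null(x$indices)) {
    cat(sprintf("  (order statistics %d and %d of n = %d)",
                x$indices[1], x$indices[2], x$n))
  } else if (!is.null(x$factor)) {
    cat(sprintf("  (mean +/- %s * sd, n = %d)",
                formatC(x$factor, format = "f", digits = digits), x$n))
  }
  cat("\n")
  invisible(x)
}
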