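# Distribution-free reference ranges from order statistics.
#
# The interval (X_[j], X_[n-j+1]) contains a random proportion of the
# population equal in distribution to a Beta(n - 2j + 1, 2j) variable
# (Tukey's equivalence-blocks result), which makes both the expected content
# and the coverage confidence available in closed form.

# guard against floating-point droop in (n+1)(1-P)/2 just below an integer
floor_eps <- function(x) floor(x + 1e-9)

#' Order-statistic depth of the distribution-free prediction interval
#'
#' The largest depth `j` such that `(X_[j], X_[n-j+1])` has expected content
#' at least P for one future observation: `j = floor((n+1)(1-P)/2)`, since
#' the expected content of the depth-j interval is `(n + 1 - 2j)/(n + 1)`.
#'
#' @param n sample size, at least 2.
#' @param content content level P in (0, 1).
#' @return An `order_indices` object with depth `j`, `n`,
#'   `kind = "prediction"` and the `attained_confidence`
#'   `Pr{content >= P}` from the beta distribution.
#' @examples
#' j_prediction(210, 0.95)  # depth 5: the interval (X_[5], X_[206])
#' @export
j_prediction <- function(n, content) {
  n <- as.integer(n)
  stopifnot(n >= 2, content > 0, content < 1)
  j <- floor_eps((n + 1) * (1 - content) / 2)
  if (j < 1) {
    n_min <- ceiling(2 / (1 - content) - 1)
    stop(sprintf(paste0("no interior prediction interval exists at n = %d, ",
                        "P = %g; need n >= %d"), n, content, n_min),
         call. = FALSE)
  }
  conf <- coverage_confidence_np(n, j, content)$confidence
  structure(list(j = as.integer(j), n = n, kind = "prediction",
                 attained_confidence = conf),
            class = "order_indices")
}

#' Coverage confidence of a depth-j order-statistic interval
#'
#' The probability that `(X_[j], X_[n-j+1])` contains at least a proportion
#' P of the population, for any continuous population: the content has the
#' Beta(n - 2j + 1, 2j) distribution, so the confidence is
#' `1 - pbeta(P, n - 2j + 1, 2j)`.
#'
#' @param n sample size, at least 2.
#' @param j order-statistic depth, `1 <= j <= n/2`.
#' @param content content level P in (0, 1).
#' @return A `beta_coverage` object with the beta shapes (`shape_a`,
#'   `shape_b`), `content` and the coverage `confidence`.
#' @examples
#' coverage_confidence_np(210, 5, 0.95)  # confidence about 0.61
#' @export
coverage_confidence_np <- function(n, j, content) {
  n <- as.integer(n); j <- as.integer(j)
  stopifnot(n >= 2, content > 0, content < 1)
  if (j < 1L || j > n / 2) {
    stop("'j' must satisfy 1 <= j <= n/2", call. = FALSE)
  }
  a <- n - 2L * j + 1L
  b <- 2L * j
  structure(list(shape_a = a, shape_b = b, content = content,
                 confidence = stats::pbeta(content, a, b,
                                           lower.tail = FALSE)),
            class = "beta_coverage")
}

#' @export
print.beta_coverage <- function(x, ...) {
  cat(sprintf(
    "Beta(%d, %d) coverage: Pr{content >= %g} = %.4f\n",
    x$shape_a, x$shape_b, x$content, x$confidence))
  invisible(x)
}

#' Order-statistic depth of the distribution-free tolerance interval
#'
#' The largest depth `j` in `1..floor(n/2)` such that `(X_[j], X_[n-j+1])`
#' contains at least a proportion P of the population with probability at
#' least gamma, found by direct search over the beta coverage condition.
#' A feasible depth exists only when `n >= minimum_n(P, gamma)`.
#'
#' @param n sample size.
#' @param spec a [range_spec()] giving P and gamma.
#' @return An `order_indices` object with `kind = "tolerance"`.
#' @examples
#' j_tolerance(210, range_spec(0.95, 0.95))  # depth 3
#' @export
j_tolerance <- function(n, spec = range_spec()) {
  n <- as.integer(n)
  stopifnot(n >= 2, inherits(spec, "range_spec"))
  j_max <- floor(n / 2)
  feasible <- vapply(seq_len(j_max), function(j) {
    coverage_confidence_np(n, j, spec$content)$confidence >= spec$confidence
  }, logical(1))
  if (!any(feasible)) {
    n_min <- minimum_n(spec$content, spec$confidence)
    stop(sprintf(paste0("no depth achieves confidence %g at n = %d, ",
                        "P = %g; need n >= %d"),
                 spec$confidence, n, spec$content, n_min),
         call. = FALSE)
  }
  j <- max(which(feasible))
  structure(list(j = as.integer(j), n = n, kind = "tolerance",
                 attained_confidence =
                   coverage_confidence_np(n, j, spec$content)$confidence),
            class = "order_indices")
}

#' @export
print.order_indices <- function(x, ...) {
  cat(sprintf(
    "%s depth j = %d (n = %d): interval (X_[%d], X_[%d]), Pr{content >= P} = %.4f\n",
    if (x$kind == "prediction") "Prediction" else "Tolerance",
    x$j, x$n, x$j, x$n - x$j + 1, x$attained_confidence))
  invisible(x)
}

#' Minimum sample size for a distribution-free tolerance interval
#'
#' The smallest `n` for which the widest order-statistic interval
#' `(X_[1], X_[n])` is a valid (P, gamma) tolerance interval, i.e. the
#' smallest `n` with `1 - (n P^(n-1) - (n-1) P^n) >= gamma`.  Powers of P
#' are evaluated in log space for numerical stability at large `n`.
#'
#' @param content content level P in (0, 1).
#' @param confidence confidence level gamma in (0, 1).
#' @return An integer sample size.
#' @examples
#' minimum_n(0.95, 0.95)  # 93, the classical distribution-free requirement
#' @export
minimum_n <- function(content, confidence) {
  stopifnot(content > 0, content < 1, confidence > 0, confidence < 1)
  lp <- log(content)
  n <- 2L
  repeat {
    conf <- 1 - (exp(log(n) + (n - 1) * lp) - exp(log(n - 1) + n * lp))
    if (conf >= confidence - 1e-12) return(n)
    n <- n + 1L
  }
}

#' Extract a depth-j order-statistic interval from data
#'
#' Sorts the data and returns the open interval between the j-th smallest
#' and j-th largest values, `(X_[j], X_[n-j+1])`, as a `reference_range`.
#' Depths are 1-based counts from each end.  Ties are permitted (real
#' laboratory data are rounded) but the beta coverage theory assumes a
#' continuous population, so a warning is emitted when more than 1% of the
#' values are tied.
#'
#' @param values numeric vector of at least 2 finite measurements.
#' @param j order-statistic depth, `1 <= j <= n/2`, e.g. from
#'   [j_prediction()] or [j_tolerance()].
#' @param method label recorded on the result, `"RR7"` (prediction) or
#'   `"RR8"` (tolerance).
#' @param spec the [range_spec()] the depth was computed for (recorded only).
#' @return A `reference_range` with the endpoints, the depth pair in
#'   `indices`, and the method tag.
#' @examples
#' extract_interval(1:10, 3)  # (3, 8)
#' @export
extract_interval <- function(values, j, method = c("RR7", "RR8"),
                             spec = range_spec()) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("'values' must be finite", call. = FALSE)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (inherits(j, "order_indices")) j <- j$j
  j <- as.integer(j)
  if (j < 1L || j > n / 2) {
    stop("'j' must satisfy 1 <= j <= n/2", call. = FALSE)
  }
  tie_frac <- 1 - length(unique(values)) / n
  if (tie_frac > 0.01) {
    warning(sprintf(paste0("%.1f%% of values are tied; distribution-free ",
                           "coverage assumes a continuous population"),
                    100 * tie_frac), call. = FALSE)
  }
  xs <- sort(values)
  new_reference_range(lower = xs[j], upper = xs[n - j + 1L],
                      factor = NA_real_, method = method, spec = spec,
                      n = n, indices = c(j, n - j + 1L))
}
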