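# Distribution of the random content K of the interval Xbar +/- c S.
#
# Conditional on the sample, K = Phi(Z/sqrt(n) + c W) - Phi(Z/sqrt(n) - c W)
# with Z ~ N(0,1) and W = sqrt(chi^2_nu / nu) independent, so K can be
# simulated directly without generating the sample itself.

# run expr under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards (no global side effects)
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate the content of the interval mean +/- c * sd
#'
#' Draws independent replicates of the random population proportion K
#' contained in `Xbar +/- c * S` for a normal sample of size `n`: each
#' replicate draws `Z ~ N(0,1)` and `chi^2_nu` (nu = n - 1) and evaluates
#' `Phi(Z/sqrt(n) + c sqrt(chi^2_nu/nu)) - Phi(Z/sqrt(n) - c sqrt(chi^2_nu/nu))`.
#' Draws are reproducible: the RNG is seeded locally and the caller's RNG
#' state is untouched.
#'
#' @param n sample size, at least 2.
#' @param c interval multiplier, `c > 0`.
#' @param reps number of replicates (default 1e6).
#' @param seed integer seed.
#' @return A `content_draws` object: list with `values` (in (0,1)), `n`,
#'   `c`, `reps`, `seed`.
#' @examples
#' d <- simulate_content(20, rr_factor("c1", 20, 0.95), reps = 1000, seed = 1)
#' mean(d$values)  # close to 0.95: E(K) = P for the prediction factor
#' @export
simulate_content <- function(n, c, reps = 1e6, seed = 1L) {
  stopifnot(n >= 2, c > 0, reps >= 1)
  nu <- n - 1
  k <- with_local_seed(seed, {
    z <- stats::rnorm(reps)
    w <- sqrt(stats::rchisq(reps, df = nu) / nu)
    stats::pnorm(z / sqrt(n) + c * w) - stats::pnorm(z / sqrt(n) - c * w)
  })
  structure(list(values = k, n = as.integer(n), c = c,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "content_draws")
}

#' Probability that an interval contains less than 100P% of the population
#'
#' The under-coverage probability `Pr{K < P}` of `Xbar +/- c * S` -- the
#' diagnostic that disqualifies prediction intervals as reference ranges.
#' The exact route is the complement of [coverage_confidence()]; the
#' simulation route estimates the same probability as the fraction of
#' simulated contents below P.
#'
#' @param n sample size, at least 2.
#' @param c interval multiplier, `c > 0`.
#' @param content content level P in (0, 1).
#' @param method `"exact"` (quadrature, default) or `"simulation"`.
#' @param reps,seed simulation controls, used only for `method = "simulation"`.
#' @return A probability.
#' @examples
#' prob_undercoverage(20, rr_factor("c1", 20, 0.95), 0.95)  # about 0.385
#' @export
prob_undercoverage <- function(n, c, content,
                               method = c("exact", "simulation"),
                               reps = 1e6, seed = 1L) {
  method <- match.arg(method)
  if (method == "exact") {
    1 - coverage_confidence(c, n, content)
  } else {
    draws <- simulate_content(n, c, reps = reps, seed = seed)
    mean(draws$values < content)
  }
}

#' Summarise simulated interval contents
#'
#' Moment and tail summaries of a set of simulated contents: mean,
#' coefficient of variation, sample skewness, excess kurtosis, the fraction
#' of replicates below the target content P, and optionally a Gaussian
#' kernel density estimate on a fixed grid over (0, 1).
#'
#' @param draws a `content_draws` object from [simulate_content()].
#' @param content target content level P in (0, 1).
#' @param density if `TRUE`, attach a 512-point kernel density estimate of
#'   the content distribution (bandwidth by Silverman's rule).
#' @return A `coverage_report`: list with `mean_content`, `cv`, `skewness`,
#'   `kurtosis` (excess), `prob_below` and optionally `density`
#'   (data frame with columns `content`, `density`).
#' @examples
#' d <- simulate_content(150, rr_factor("c1", 150, 0.95), reps = 1e4, seed = 2)
#' summarize_content(d, 0.95)
#' @export
summarize_content <- function(draws, content, density = FALSE) {
  stopifnot(inherits(draws, "content_draws"),
            content > 0, content < 1)
  k <- draws$values
  if (length(k) < 2L) stop("need at least 2 draws", call. = FALSE)
  m <- mean(k)
  s <- stats::sd(k)
  if (s == 0) stop("degenerate draws: zero variance", call. = FALSE)
  cent <- k - m
  m2 <- mean(cent^2)
  rep <- structure(list(
    mean_content = m,
    cv = s / m,
    skewness = mean(cent^3) / m2^1.5,
    kurtosis = mean(cent^4) / m2^2 - 3,
    prob_below = mean(k < content),
    n = draws$n, c = draws$c, reps = draws$reps,
    density = NULL), class = "coverage_report")
  if (density) {
    de <- stats::density(k, n = 512, from = max(1e-4, min(k)),
                         to = min(1 - 1e-6, max(k)))
    rep$density <- data.frame(content = de$x, density = de$y)
  }
  rep
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "Content distribution (n = %d, c = %.4f, %d reps):\n", x$n, x$c, x$reps))
  cat(sprintf("  mean %.4f, CV %.4f, skewness %.2f, excess kurtosis %.2f\n",
              x$mean_content, x$cv, x$skewness, x$kurtosis))
  cat(sprintf("  Pr{content < P} = %.3f\n", x$prob_below))
  invisible(x)
}

#' Under-coverage of the prediction interval along a grid of sample sizes
#'
#' Computes `Pr{K < P}` for the P prediction interval (`c = c1(n, P)`) at
#' each sample size in `n_grid`, by exact quadrature.  The probability is
#' below 1/2 for every finite `n`, increases with `n`, and tends to 1/2 --
#' larger samples make the prediction interval *more* likely to fail as a
#' reference range, not less.
#'
#' @param n_grid increasing vector of sample sizes (each >= 2).
#' @param content content level P in (0, 1).
#' @return Numeric vector of under-coverage probabilities, one per grid
#'   point, named by `n`.
#' @examples
#' asymptotic_check(c(20, 50, 100, 150), 0.95)
#' @export
asymptotic_check <- function(n_grid, content) {
  stopifnot(all(n_grid >= 2), !is.unsorted(n_grid))
  out <- vapply(n_grid, function(n) {
    prob_undercoverage(n, rr_factor("c1", n, content), content)
  }, numeric(1))
  names(out) <- n_grid
  out
}
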