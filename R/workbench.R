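# End-to-end analysis: input handling, synthetic fixtures, per-method
# reports, and the curve tables behind the factor / under-coverage / depth
# comparisons.

#' Analysis configuration
#'
#' Bundles the knobs of [run_analysis()]: the target content P and
#' confidence gamma, which reference-range methods to compute, the
#' reporting precision, and simulation controls.
#'
#' @param content content level P in (0, 1).  Default 0.95.
#' @param confidence confidence level gamma in (0, 1).  Default 0.95.
#' @param methods character subset of `"RR1"` ... `"RR8"`:
#'   RR1 normal prediction interval; RR2-RR4 percentile plug-in estimators;
#'   RR5 two-sided tolerance interval; RR6 equal-tailed tolerance interval;
#'   RR7 distribution-free prediction interval; RR8 distribution-free
#'   tolerance interval.
#' @param decimals reporting precision for interval endpoints (default 2;
#'   internal computation is always full double precision).
#' @param seed integer seed for any simulation-based diagnostic.
#' @param reps replicate count for simulation-based diagnostics.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(content = 0.95, confidence = 0.95,
                            methods = c("RR1", "RR5", "RR6", "RR7", "RR8"),
                            decimals = 2L, seed = 1L, reps = 1e6) {
  all_m <- paste0("RR", 1:8)
  methods <- as.character(methods)
  if (!all(methods %in% all_m)) {
    stop("unknown method(s): ",
         paste(setdiff(methods, all_m), collapse = ", "), call. = FALSE)
  }
  spec <- range_spec(content, confidence)  # validates both
  structure(list(content = content, confidence = confidence,
                 methods = methods, decimals = as.integer(decimals),
                 seed = as.integer(seed), reps = as.integer(reps),
                 spec = spec),
            class = "analysis_config")
}

#' Read marker values from a delimited text file
#'
#' Reads a single- or named-column CSV/TSV file of measurements.  The
#' delimiter is sniffed from the first line (tab, then comma, else
#' whitespace) and a header row is auto-detected when its fields do not
#' parse as numbers.  Parsing is strict: any non-numeric or missing cell in
#' the chosen column is a hard error naming the offending row, since a
#' silently dropped value changes every order statistic.
#'
#' @param path path to the file.
#' @param column optional column name (or 1-based index); default first
#'   column.
#' @return Numeric vector of finite values in file order.
#' @export
read_values <- function(path, column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("file is empty: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1]])) "\t"
         else if (grepl(",", lines[[1]])) "," else ""
  first <- strsplit(lines[[1]], if (sep == "") "[[:space:]]+" else sep)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(text = lines, sep = sep, header = has_header,
                          colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  if (is.null(column)) {
    col <- df[[1L]]
  } else if (is.character(column)) {
    if (!column %in% names(df)) {
      stop("column '", column, "' not found; available: ",
           paste(names(df), collapse = ", "), call. = FALSE)
    }
    col <- df[[column]]
  } else {
    col <- df[[as.integer(column)]]
  }
  if (length(col) == 0L) stop("chosen column is empty", call. = FALSE)
  vals <- suppressWarnings(as.numeric(col))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at data row %d of %s",
                 col[bad[1]], bad[1], path), call. = FALSE)
  }
  message(sprintf("read %d values from %s (min %g, max %g)",
                  length(vals), path, min(vals), max(vals)))
  vals
}

#' Generate a synthetic sample of marker values
#'
#' Draws `n` values from a chosen population family, for exercising the
#' reference-range methods without access to patient data.
#'
#' Families:
#' \describe{
#'   \item{`normal`}{`N(mu, sigma^2)`.  With `exact_moments = TRUE` the draw
#'     is affinely rescaled so the sample mean and (n-1)-denominator SD equal
#'     `mu` and `sigma` *exactly* -- every normal-theory interval computed
#'     from the sample then reproduces, bit for bit, the intervals computed
#'     from the printed summary statistics.}
#'   \item{`lognormal`}{log-normal parameterised so the population mean and
#'     SD are `mu` and `sigma`; right-skewed, as many enzyme and hormone
#'     markers are.}
#'   \item{`mixture`}{contaminated normal, `0.9 N(mu, sigma^2) +
#'     0.1 N(mu, (3 sigma)^2)`: symmetric but heavy-tailed.}
#' }
#'
#' @param n sample size, at least 2.
#' @param mu target mean, marker units.
#' @param sigma target standard deviation, marker units, positive.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param exact_moments standardise the sample to the exact target moments
#'   (normal family only).
#' @param family `"normal"`, `"lognormal"` or `"mixture"`.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- generate_fixture(210, 5.31, 0.41, seed = 1, exact_moments = TRUE)
#' summarize_sample(x)  # exactly mean 5.31, sd 0.41
#' @export
generate_fixture <- function(n, mu, sigma, seed = 1L, exact_moments = FALSE,
                             family = c("normal", "lognormal", "mixture")) {
  family <- match.arg(family)
  stopifnot(n >= 2, sigma > 0)
  if (exact_moments && family != "normal") {
    stop("'exact_moments' applies to the normal family only", call. = FALSE)
  }
  x <- with_local_seed(seed, switch(family,
    normal = stats::rnorm(n, mu, sigma),
    lognormal = {
      sdlog <- sqrt(log(1 + (sigma / mu)^2))
      stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    },
    mixture = {
      heavy <- stats::runif(n) < 0.1
      stats::rnorm(n, mu, ifelse(heavy, 3 * sigma, sigma))
    }))
  if (exact_moments) {
    x <- (x - mean(x)) / stats::sd(x) * sigma + mu
  }
  x
}

#' Compute reference ranges with their coverage diagnostics
#'
#' Runs the requested reference-range methods on either raw values or a
#' [sample_summary()] and attaches to each interval the diagnostic the
#' method calls for:
#' * RR1-RR4 and RR7 (prediction / plug-in intervals): the under-coverage
#'   probability `Pr{content < P}`, computed exactly;
#' * RR5 (two-sided tolerance): the achieved confidence and the probability
#'   of containing the *central* 100P% band of the population;
#' * RR6 (equal-tailed tolerance): the achieved central-containment
#'   confidence, the probability that content is at least P, and the content
#'   level the factor guarantees at confidence gamma;
#' * RR8 (distribution-free tolerance): the attained confidence of the
#'   selected depth.
#'
#' The distribution-free methods RR7/RR8 need the raw values; requesting
#' them with summary-only input is an error.
#'
#' @param x numeric vector of measurements, or a [sample_summary()].
#' @param config an [analysis_config()].
#' @return A `range_report`: list with `ranges` (named list of
#'   `reference_range`s), `diagnostics` (data frame, one row per method),
#'   `summary`, `config` and `provenance`.
#' @examples
#' s <- sample_summary(210, 5.31, 0.41)
#' run_analysis(s, analysis_config(methods = c("RR1", "RR5", "RR6")))
#' @export
run_analysis <- function(x, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (inherits(x, "sample_summary")) {
    values <- NULL
    summary <- x
    input <- sprintf("summary(n=%d, mean=%g, sd=%g)", x$n, x$mean, x$sd)
  } else {
    values <- as.numeric(x)
    summary <- summarize_sample(values)
    input <- sprintf("values(n=%d)", length(values))
  }
  np_requested <- intersect(config$methods, c("RR7", "RR8"))
  if (length(np_requested) > 0L && is.null(values)) {
    stop("methods ", paste(np_requested, collapse = ", "),
         " need raw values; summary statistics are not sufficient",
         call. = FALSE)
  }
  spec <- config$spec
  ranges <- list()
  diag_rows <- list()
  for (m in config$methods) {
    if (m %in% paste0("RR", 1:6)) {
      rng <- build_range(m, summary, spec)
    } else if (m == "RR7") {
      jp <- j_prediction(summary$n, spec$content)
      rng <- extract_interval(values, jp, method = "RR7", spec = spec)
      rng$attained_confidence <- jp$attained_confidence
    } else {
      jt <- j_tolerance(summary$n, spec)
      rng <- extract_interval(values, jt, method = "RR8", spec = spec)
      rng$attained_confidence <- jt$attained_confidence
    }
    d <- list(method = m, lower = rng$lower, upper = rng$upper,
              factor = if (is.null(rng$indices)) rng$factor else NA_real_,
              depth = if (is.null(rng$indices)) NA_integer_ else
                rng$indices[1],
              prob_undercoverage = NA_real_,
              achieved_confidence = NA_real_,
              central_containment = NA_real_,
              content_at_confidence = NA_real_)
    if (m %in% c("RR1", "RR2", "RR3", "RR4")) {
      d$prob_undercoverage <-
        prob_undercoverage(summary$n, rng$factor, spec$content)
    } else if (m == "RR5") {
      d$achieved_confidence <-
        coverage_confidence(rng$factor, summary$n, spec$content)
      d$central_containment <-
        central_coverage_confidence(rng$factor, summary$n, spec$content)
    } else if (m == "RR6") {
      d$achieved_confidence <-
        coverage_confidence(rng$factor, summary$n, spec$content)
      d$central_containment <-
        central_coverage_confidence(rng$factor, summary$n, spec$content)
      d$content_at_confidence <-
        content_for_factor(rng$factor, summary$n, spec$confidence)
    } else if (m == "RR7") {
      d$prob_undercoverage <- 1 - rng$attained_confidence
    } else if (m == "RR8") {
      d$achieved_confidence <- rng$attained_confidence
    }
    ranges[[m]] <- rng
    diag_rows[[m]] <- as.data.frame(d)
  }
  structure(list(
    ranges = ranges,
    diagnostics = if (length(diag_rows)) do.call(rbind, diag_rows)
                  else data.frame(),
    summary = summary,
    config = config,
    provenance = list(input = input,
                      package = "refrange",
                      version = as.character(
                        utils::packageVersion("refrange")))),
    class = "range_report")
}

#' @export
print.range_report <- function(x, ...) {
  dec <- x$config$decimals
  fmt <- function(v) formatC(v, format = "f", digits = dec)
  pct <- function(p) sprintf("%.0f%%", 100 * p)
  s <- x$summary
  cat(sprintf("Reference range analysis (%s; P = %g, gamma = %g)\n",
              x$provenance$input, x$config$content, x$config$confidence))
  if (nrow(x$diagnostics) == 0L) {
    cat("  no methods requested\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$diagnostics))) {
    d <- x$diagnostics[i, ]
    cat(sprintf("  %s = [%s, %s]", d$method, fmt(d$lower), fmt(d$upper)))
    if (!is.na(d$factor)) cat(sprintf("  (c = %s)", fmt(d$factor)))
    if (!is.na(d$depth)) cat(sprintf("  (depth j = %d)", d$depth))
    cat("\n")
    if (!is.na(d$prob_undercoverage)) {
      cat(sprintf(paste0("      with probability %s this interval contains",
                         " less than %g%% of the population\n"),
                  pct(d$prob_undercoverage), 100 * x$config$content))
    }
    if (!is.na(d$achieved_confidence)) {
      cat(sprintf("      contains >= %g%% of the population with probability %s\n",
                  100 * x$config$content, pct(d$achieved_confidence)))
    }
    if (!is.na(d$central_containment)) {
      cat(sprintf("      contains the central %g%% band with probability %s\n",
                  100 * x$config$content, pct(d$central_containment)))
    }
    if (!is.na(d$content_at_confidence)) {
      cat(sprintf("      guarantees %.1f%% content at confidence %g%%\n",
                  100 * d$content_at_confidence, 100 * x$config$confidence))
    }
  }
  invisible(x)
}

#' Write a range report to disk
#'
#' @param report a `range_report` from [run_analysis()].
#' @param path output file path.
#' @param format `"json"` (versioned schema), `"tsv"` (the diagnostics
#'   table) or `"text"` (the printed narrative).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "range_report"))
  if (format == "json") {
    payload <- list(
      schema = "refrange/report/v1",
      content = report$config$content,
      confidence = report$config$confidence,
      sample = list(n = report$summary$n, mean = report$summary$mean,
                    sd = report$summary$sd),
      methods = report$diagnostics,
      provenance = report$provenance)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else if (format == "tsv") {
    utils::write.table(report$diagnostics, path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    sink(path)
    on.exit(sink())
    print(report)
  }
  invisible(path)
}

#' Tabulate factor, under-coverage or depth curves against sample size
#'
#' Recomputes, as plain tables, the quantities usually shown as curves
#' against the sample size: the normal-theory multipliers c1-c6, the exact
#' under-coverage probability of the prediction interval, or the
#' distribution-free depths j(p) and j(t).
#'
#' @param kind `"factors"` (columns c1..c6), `"undercoverage"`
#'   (`Pr{content < P}` for the prediction factor c1), or `"indices"`
#'   (depths `j_p` and `j_t`; `j_t` is `NA` where no depth is feasible).
#' @param n_range vector of sample sizes (each >= 2).
#' @param content content level P in (0, 1).
#' @param confidence confidence level gamma (used by c5, c6 and `j_t`).
#' @param tolerance_factors for `kind = "factors"`, also solve the c5/c6
#'   tolerance factors at each n (slower); `TRUE` by default.
#' @return A data frame with one row per sample size.
#' @examples
#' emit_curves("undercoverage", c(20, 50, 100, 150), content = 0.95)
#' @export
emit_curves <- function(kind = c("factors", "undercoverage", "indices"),
                        n_range, content = 0.95, confidence = 0.95,
                        tolerance_factors = TRUE) {
  kind <- match.arg(kind)
  stopifnot(all(n_range >= 2))
  n_range <- as.integer(n_range)
  spec <- range_spec(content, confidence)
  if (kind == "factors") {
    out <- data.frame(
      n = n_range,
      c1 = vapply(n_range, rr_factor, numeric(1), method = "c1",
                  content = content),
      c2 = vapply(n_range, rr_factor, numeric(1), method = "c2",
                  content = content),
      c3 = vapply(n_range, rr_factor, numeric(1), method = "c3",
                  content = content),
      c4 = vapply(n_range, rr_factor, numeric(1), method = "c4",
                  content = content))
    if (tolerance_factors) {
      out$c5 <- vapply(n_range,
                       function(n) two_sided_factor(n, spec)$factor,
                       numeric(1))
      out$c6 <- vapply(n_range,
                       function(n) equal_tailed_factor(n, spec)$factor,
                       numeric(1))
    }
    out
  } else if (kind == "undercoverage") {
    data.frame(n = n_range,
               prob_undercoverage = unname(asymptotic_check(sort(n_range),
                                                            content)))
  } else {
    jp <- vapply(n_range, function(n) {
      tryCatch(j_prediction(n, content)$j, error = function(e) NA_integer_)
    }, integer(1))
    jt <- vapply(n_range, function(n) {
      tryCatch(j_tolerance(n, spec)$j, error = function(e) NA_integer_)
    }, integer(1))
    data.frame(n = n_range, j_p = jp, j_t = jt)
  }
}
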