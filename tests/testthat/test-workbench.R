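test_that("read_values parses bare, headed, and named-column files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("5.1", "5.2", "5.3"), f)
  expect_message(v <- read_values(f), "read 3 values")
  expect_equal(v, c(5.1, 5.2, 5.3))

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("glucose,site", "5.1,A", "5.4,B"), g)
  expect_equal(suppressMessages(read_values(g, column = "glucose")),
               c(5.1, 5.4))

  h <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tvalue", "1\t4.9", "2\t5.6"), h)
  expect_equal(suppressMessages(read_values(h, column = "value")),
               c(4.9, 5.6))
})

test_that("read_values is strict about missing and malformed cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("5.1", "NA", "5.3"), f)
  expect_error(read_values(f), "row 2")
  expect_error(read_values(file.path(tempdir(), "no-such-file.csv")),
               "not found")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("glucose", "5.1", "oops"), g)
  expect_error(read_values(g), "oops")
})

test_that("fixtures are deterministic and match their family", {
  x1 <- generate_fixture(100, 5, 1, seed = 7)
  x2 <- generate_fixture(100, 5, 1, seed = 7)
  expect_identical(x1, x2)
  expect_false(identical(x1, generate_fixture(100, 5, 1, seed = 8)))

  ex <- generate_fixture(210, 5.31, 0.41, seed = 1, exact_moments = TRUE)
  expect_equal(mean(ex), 5.31)
  expect_equal(sd(ex), 0.41)

  ln <- generate_fixture(1e4, 5, 2, seed = 9, family = "lognormal")
  skew <- mean((ln - mean(ln))^3) / sd(ln)^3
  expect_gt(skew, 0)
  expect_true(all(ln > 0))

  mx <- generate_fixture(1e4, 5, 1, seed = 9, family = "mixture")
  kurt <- mean((mx - mean(mx))^4) / sd(mx)^4 - 3
  expect_gt(kurt, 0)

  expect_error(generate_fixture(50, 5, 1, exact_moments = TRUE,
                                family = "lognormal"), "normal")
})

test_that("run_analysis reproduces the glucose example with diagnostics", {
  s <- sample_summary(210, 5.31, 0.41)
  rep <- run_analysis(s, analysis_config(methods = c("RR1", "RR5", "RR6")))
  d <- rep$diagnostics
  expect_equal(d$method, c("RR1", "RR5", "RR6"))
  expect_lt(max(abs(d$lower - c(4.49, 4.43, 4.40))), 0.0105)
  expect_lt(max(abs(d$upper - c(6.12, 6.19, 6.22))), 0.0105)
  expect_equal(round(100 * d$prob_undercoverage[1]), 47)
  expect_equal(round(100 * d$central_containment[2]), 86)
  expect_equal(round(100 * d$achieved_confidence[3]), 99)
  expect_equal(round(100 * d$content_at_confidence[3], 1), 95.7)
  out <- capture.output(print(rep))
  expect_true(any(grepl("probability 47% this interval contains less",
                        out)))
})

test_that("run_analysis guards summary-only and infeasible requests", {
  s <- sample_summary(210, 5.31, 0.41)
  expect_error(run_analysis(s, analysis_config(methods = c("RR1", "RR7"))),
               "raw values")
  x <- generate_fixture(50, 5, 1, seed = 2)
  expect_error(run_analysis(x, analysis_config(methods = "RR8")), "93")
  empty <- run_analysis(s, analysis_config(methods = character(0)))
  expect_equal(nrow(empty$diagnostics), 0)
  expect_match(empty$provenance$input, "summary")
})

test_that("reports are deterministic and serialisable", {
  x <- generate_fixture(210, 5.31, 0.41, seed = 4, exact_moments = TRUE)
  cfg <- analysis_config()
  r1 <- run_analysis(x, cfg)
  r2 <- run_analysis(x, cfg)
  expect_identical(capture.output(print(r1)), capture.output(print(r2)))
  expect_true(all(r1$diagnostics$lower < r1$diagnostics$upper))
  # nonparametric endpoints are members of the data
  expect_true(r1$ranges$RR7$lower %in% x && r1$ranges$RR7$upper %in% x)

  jf <- withr::local_tempfile(fileext = ".json")
  write_report(r1, jf, format = "json")
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$schema, "refrange/report/v1")
  expect_length(parsed$methods, nrow(r1$diagnostics))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_report(r1, tf, format = "tsv")
  expect_equal(nrow(utils::read.delim(tf)), nrow(r1$diagnostics))
  xf <- withr::local_tempfile(fileext = ".txt")
  write_report(r1, xf, format = "text")
  expect_identical(readLines(xf), capture.output(print(r1)))
})

test_that("emit_curves tabulates factors, under-coverage and depths", {
  fac <- emit_curves("factors", c(5, 20, 60), content = 0.95)
  expect_true(all(fac$c1 > pmax(fac$c2, fac$c4)))
  expect_true(all(fac$c3 > fac$c2))
  expect_true(all(fac$c6 > fac$c5 & fac$c5 > fac$c1))

  uc <- emit_curves("undercoverage", c(20, 50, 100, 150), content = 0.95)
  expect_equal(round(uc$prob_undercoverage, 3), c(0.385, 0.429, 0.450, 0.459))

  idx <- emit_curves("indices", seq(90, 300, by = 30))
  expect_true(all(diff(idx$j_p) >= 0))           # saw-tooth, nondecreasing
  expect_true(is.na(emit_curves("indices", 50)$j_t))  # below minimum n
  expect_true(all(idx$j_t <= idx$j_p, na.rm = TRUE))
})

test_that("the command-line script exposes the analysis verbs", {
  cli <- system.file("cli", "refrange.R", package = "refrange")
  expect_true(nzchar(cli) && file.exists(cli))
  expect_true(any(grepl("range|curves", readLines(cli))))
})
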