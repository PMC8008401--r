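test_that("j_prediction computes the integer-part depth", {
  expect_equal(j_prediction(210, 0.95)$j, 5L)
  expect_equal(j_prediction(39, 0.95)$j, 1L)
  # (n+1)(1-P)/2 = 1 exactly; floating-point droop must not push it to 0
  expect_equal(j_prediction(19, 0.90)$j, 1L)
  expect_error(j_prediction(20, 0.99), "need n >=")
})

test_that("beta coverage confidence matches the order-statistic law", {
  bc <- coverage_confidence_np(210, 5, 0.95)
  expect_equal(bc$shape_a, 201L)
  expect_equal(bc$shape_b, 10L)
  expect_equal(bc$confidence, 1 - pbeta(0.95, 201, 10), tolerance = 1e-12)
  expect_gte(coverage_confidence_np(210, 3, 0.95)$confidence, 0.95)
  expect_error(coverage_confidence_np(20, 11, 0.95), "j")
  # independent oracle: simulate uniform order statistics
  mc <- mc_np_coverage(50, 2, 0.9, reps = 2e4, seed = 5)
  expect_lt(abs(coverage_confidence_np(50, 2, 0.9)$confidence - mc$p),
            3 * mc$se)
})

test_that("coverage confidence falls as depth or content grows", {
  confs_j <- vapply(1:10, function(j) {
    coverage_confidence_np(100, j, 0.9)$confidence
  }, numeric(1))
  expect_true(all(diff(confs_j) < 0))
  confs_p <- vapply(c(0.8, 0.9, 0.95, 0.99), function(P) {
    coverage_confidence_np(100, 2, P)$confidence
  }, numeric(1))
  expect_true(all(diff(confs_p) < 0))
})

test_that("j_tolerance searches the beta condition and flags infeasibility", {
  jt <- j_tolerance(210, range_spec(0.95, 0.95))
  expect_equal(jt$j, 3L)
  expect_gte(jt$attained_confidence, 0.95)
  # one deeper would violate the confidence requirement
  expect_lt(coverage_confidence_np(210, 4, 0.95)$confidence, 0.95)
  expect_lte(jt$j, j_prediction(210, 0.95)$j)
  expect_error(j_tolerance(50, range_spec(0.95, 0.95)), "93")
})

test_that("minimum_n reproduces classical sample-size requirements", {
  expect_equal(minimum_n(0.95, 0.95), 93L)
  expect_equal(minimum_n(0.5, 0.5), 3L)
  # brute-force oracle via the j = 1 beta coverage
  oracle <- function(P, g) {
    for (n in 2:2000) {
      if (1 - pbeta(P, n - 1, 2) >= g - 1e-12) return(n)
    }
  }
  for (P in c(0.8, 0.9, 0.95)) {
    for (g in c(0.8, 0.9, 0.95)) {
      expect_equal(minimum_n(P, g), oracle(P, g))
    }
  }
  # nondecreasing in both arguments
  grid_p <- vapply(c(0.8, 0.9, 0.95, 0.99), minimum_n, integer(1),
                   confidence = 0.9)
  grid_g <- vapply(c(0.8, 0.9, 0.95, 0.99), function(g) {
    minimum_n(0.9, g)
  }, integer(1))
  expect_true(all(diff(grid_p) >= 0))
  expect_true(all(diff(grid_g) >= 0))
})

test_that("extract_interval returns the depth-j order statistics", {
  r1 <- extract_interval(10:1, 1)
  expect_equal(c(r1$lower, r1$upper), c(1, 10))
  r3 <- extract_interval(sample(1:10), 3)
  expect_equal(c(r3$lower, r3$upper), c(3, 8))
  expect_equal(r3$indices, c(3L, 8L))
  # ties: depth counting still picks the j-th smallest / largest
  x <- c(2, 2, 2, 5, 7, 7, 9, 9, 9, 9)
  expect_warning(r <- extract_interval(x, 2), "tied")
  expect_equal(c(r$lower, r$upper), c(2, 9))
  expect_error(extract_interval(1:10, 6), "j")
})

test_that("tolerance depth gives a wider interval than prediction depth", {
  set.seed(8)
  x <- rnorm(210)
  jp <- j_prediction(210, 0.95)
  jt <- j_tolerance(210, range_spec(0.95, 0.95))
  rp <- extract_interval(x, jp, method = "RR7")
  rt <- extract_interval(x, jt, method = "RR8")
  expect_lte(rt$lower, rp$lower)
  expect_gte(rt$upper, rp$upper)
})

test_that("prediction-depth coverage confidence approaches 1/2 from above", {
  # saw-tooth in n, but pinned near 1/2 for large n
  conf <- coverage_confidence_np(1e5, j_prediction(1e5, 0.95)$j,
                                 0.95)$confidence
  expect_lte(conf, 0.55)
  expect_gte(conf, 0.45)
  for (n in c(210, 1000, 10000)) {
    j <- j_prediction(n, 0.95)$j
    expect_gt(coverage_confidence_np(n, j, 0.95)$confidence, 0.5)
  }
})
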