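test_that("point estimate is the sample median", {
  expect_equal(point_estimate(c(1, 1, 1)), 1)
  expect_equal(point_estimate(c(0.5, 1, 2)), 1)
  expect_error(point_estimate(numeric(0)), "empty")
  set.seed(41)
  x <- exp(rnorm(10001, 0.2, 0.3))
  expect_equal(point_estimate(x), exp(0.2), tolerance = 0.02)
})

test_that("credible intervals are equal-tailed type-7 quantiles", {
  expect_equal(credible_interval(c(2, 2, 2), 80), c(2, 2))
  set.seed(42)
  x <- exp(rnorm(10001))
  ci <- credible_interval(x, 80)
  expect_equal(ci, exp(c(-1, 1) * qnorm(0.9)), tolerance = 0.05)
  # level -> 100 limit approaches (min, max)
  expect_equal(credible_interval(x, 100 - 1e-9), range(x), tolerance = 1e-4)
  expect_error(credible_interval(x, 0), "level")
  expect_error(credible_interval(x, 100), "level")
  # independent quantile oracle
  expect_equal(credible_interval(x, 60),
               unname(quantile(x, c(0.2, 0.8))))
})

test_that("ppd counts draws above the reference of 1, ties as half", {
  expect_equal(ppd(c(2, 2, 2)), 1)
  expect_equal(ppd(c(0.5, 2)), 0.5)
  expect_equal(ppd(c(1, 2)), 0.75)  # tie counted half
  expect_error(ppd(numeric(0)), "empty")
  set.seed(43)
  x <- exp(rnorm(1e5, 0.1, 0.2))
  expect_equal(ppd(x), pnorm(0.1 / 0.2), tolerance = 0.01)
  expect_equal(ppd(x), mean(x > 1))  # brute-force count
})

test_that("folded confidence and category thresholds behave", {
  expect_equal(v_confidence(c(0.5, 0.9, 0.2)), c(0.5, 0.9, 0.8))
  expect_error(v_confidence(1.2), "\\[0, 1\\]")
  p <- seq(0, 1, by = 0.05)
  expect_equal(v_confidence(p), v_confidence(1 - p))
  expect_equal(classify_difference(c(0.95, 0.05, 0.5)),
               c("likely_higher", "likely_lower", "uncertain"))
  expect_equal(classify_difference(0.5, thresholds = c(0.45, 0.5)),
               "likely_higher")
  expect_error(classify_difference(0.5, thresholds = c(0.8, 0.2)),
               "thresholds")
})

test_that("summarize_all matches an independent per-area loop", {
  set.seed(44)
  mat <- matrix(exp(rnorm(500 * 4, rep(c(-0.3, 0, 0.2, 0.6), each = 500),
                          0.25)), 500, 4)
  colnames(mat) <- paste0("z", 1:4)
  s <- summarize_all(mat)
  expect_equal(s$area_id, paste0("z", 1:4))
  for (k in 1:4) {
    x <- mat[, k]
    expect_equal(s$point[k], unname(quantile(x, 0.5)))
    expect_equal(s$ci80_lo[k], unname(quantile(x, 0.1)))
    expect_equal(s$ci80_hi[k], unname(quantile(x, 0.9)))
    expect_equal(s$ci60_lo[k], unname(quantile(x, 0.2)))
    expect_equal(s$ppd[k], mean(x > 1) + 0.5 * mean(x == 1))
    expect_equal(s$v_conf[k], max(s$ppd[k], 1 - s$ppd[k]))
  }
  # all-constant draws at the reference
  s1 <- summarize_all(matrix(1, 100, 1, dimnames = list(NULL, "c")))
  expect_equal(s1$ppd, 0.5)
  expect_equal(s1$ci80_lo, s1$ci80_hi)
})

test_that("intervals nest and contain the median on arbitrary draws", {
  set.seed(45)
  for (k in 1:10) {
    x <- exp(rnorm(211, runif(1, -1, 1), runif(1, 0.05, 1)))
    s <- summarize_all(matrix(x, dimnames = list(NULL, "a")))
    expect_lte(s$ci80_lo, s$ci60_lo)
    expect_lte(s$ci60_lo, s$point)
    expect_lte(s$point, s$ci60_hi)
    expect_lte(s$ci60_hi, s$ci80_hi)
  }
})

test_that("ppd is monotone under multiplicative upward shifts", {
  set.seed(46)
  for (k in 1:10) {
    x <- exp(rnorm(97, 0, 0.5))
    shift <- exp(runif(1, 0, 1))
    expect_gte(ppd(x * shift), ppd(x))
  }
})

test_that("summary CSV round-trips at the documented precision", {
  set.seed(47)
  mat <- matrix(exp(rnorm(300 * 3, 0, 0.3)), 300, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  s <- summarize_all(mat)
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(s, path)
  s2 <- read_summary_csv(path)
  expect_equal(s2$area_id, s$area_id)
  expect_equal(s2$point, s$point, tolerance = 1e-5)
  expect_equal(s2$ppd, s$ppd, tolerance = 1e-5)
  expect_identical(s2$category, s$category)
})
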