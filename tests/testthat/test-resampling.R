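# Independent type-7 quantile oracle: h = (n-1)p + 1, linear interpolation
# between the flooring order statistics.
quantileOracle <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

test_that("percentile CI matches the linear-interpolation quantile formula", {
  expect_equal(percentileCI(5, 0.05), c(low = 5, high = 5))
  s <- as.numeric(1:100)
  ci <- percentileCI(s, 0.05)
  expect_equal(unname(ci), c(quantileOracle(s, 0.025),
                             quantileOracle(s, 0.975)))
  set.seed(701)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:40, 1))
    a <- stats::runif(1, 0.01, 0.5)
    ci <- percentileCI(x, a)
    expect_equal(unname(ci), c(quantileOracle(x, a / 2),
                               quantileOracle(x, 1 - a / 2)))
  }
  # alpha -> 1: both bounds converge to the median
  ci <- percentileCI(s, 1 - 1e-9)
  expect_equal(unname(ci), rep(stats::median(s), 2), tolerance = 1e-6)
})

test_that("the exhaustive oracle enumerates the documented toy null exactly", {
  r <- exhaustiveNull(c(10, 10), c(0, 1, 2, 3), null = "absences")
  expect_equal(sort(r@nullMeans), c(0.5, 1.0, 1.5, 1.5, 2.0, 2.5))
  expect_equal(r@presenceMean, 10)
  expect_true(r@significant)
  expect_equal(r@direction, "higher")
  expect_equal(r@B, 6L)
  # same verdict from the Monte-Carlo route at large B
  mc <- balancedResamplingTest(c(10, 10), c(0, 1, 2, 3), B = 20000,
                               seed = 7, null = "absences")
  expect_true(mc@significant)
  expect_equal(mc@direction, "higher")
  # under the pooled null the presence pair itself enters the pool, so the
  # null has an atom at 10 and the presence mean only ties the upper bound
  mcP <- balancedResamplingTest(c(10, 10), c(0, 1, 2, 3), B = 20000,
                                seed = 7, null = "pooled")
  expect_false(mcP@significant)
  expect_equal(max(mcP@nullMeans), 10)
})

test_that("degenerate and capacity edge cases behave as documented", {
  # all values identical: CI collapses, nothing can be significant
  r <- balancedResamplingTest(rep(3, 7), rep(3, 37), B = 500, seed = 1)
  expect_equal(c(r@ciLow, r@ciHigh), c(3, 3))
  expect_false(r@significant)
  expect_equal(r@direction, "none")
  # n_p = n_a under the absences null: single subset, degenerate CI
  r1 <- exhaustiveNull(c(1, 2), c(5, 7), null = "absences")
  expect_equal(r1@B, 1L)
  expect_equal(c(r1@ciLow, r1@ciHigh), c(6, 6))
  expect_error(exhaustiveNull(rep(1, 15), rnorm(60)), "cap")
  expect_error(balancedResamplingTest(1:5, 1:3), "balanced")
  expect_error(balancedResamplingTest(c(1, NA), 1:5), "finite")
  expect_error(balancedResamplingTest(numeric(0), 1:5), "presence")
  expect_error(balancedResamplingTest(1, 1:5, alpha = 1.2), "alpha")
})

test_that("results are reproducible given the seed and shift-equivariant", {
  set.seed(702)
  p <- stats::rnorm(7); a <- stats::rnorm(37)
  r1 <- balancedResamplingTest(p, a, B = 2000, seed = 42)
  r2 <- balancedResamplingTest(p, a, B = 2000, seed = 42)
  expect_identical(r1@nullMeans, r2@nullMeans)
  expect_identical(resamplingSummary(list(r1)), resamplingSummary(list(r2)))
  r3 <- balancedResamplingTest(p, a, B = 2000, seed = 43)
  expect_false(identical(r1@nullMeans, r3@nullMeans))
  # adding c shifts the mean and both bounds by exactly c, verdict unchanged
  cshift <- 17.25
  r4 <- balancedResamplingTest(p + cshift, a + cshift, B = 2000, seed = 42)
  expect_equal(r4@presenceMean, r1@presenceMean + cshift)
  expect_equal(r4@ciLow, r1@ciLow + cshift)
  expect_equal(r4@ciHigh, r1@ciHigh + cshift)
  expect_identical(r4@direction, r1@direction)
  # the test must not disturb the caller's RNG stream
  set.seed(9); before <- stats::runif(1)
  set.seed(9); invisible(balancedResamplingTest(p, a, B = 50, seed = 1))
  expect_identical(stats::runif(1), before)
})

test_that("Monte-Carlo CI bounds agree with full enumeration for small pools", {
  set.seed(703)
  p <- stats::rnorm(4); a <- stats::rnorm(12)
  for (mode in c("pooled", "absences")) {
    ex <- exhaustiveNull(p, a, null = mode)
    mc <- balancedResamplingTest(p, a, B = 20000, seed = 11, null = mode)
    expect_true(mcQuantileAgrees(ex@nullMeans, 0.025, mc@ciLow, 20000))
    expect_true(mcQuantileAgrees(ex@nullMeans, 0.975, mc@ciHigh, 20000))
  }
})

test_that("the pooled null holds its nominal size in a small calibration run", {
  set.seed(704)
  R <- 400
  rej <- vapply(seq_len(R), function(i) {
    p <- stats::rnorm(7); a <- stats::rnorm(37)
    balancedResamplingTest(p, a, B = 600, seed = i)@significant
  }, logical(1))
  rate <- mean(rej)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.10)
})

test_that("the absences-only null is measurably anti-conservative", {
  set.seed(705)
  R <- 300
  rej <- vapply(seq_len(R), function(i) {
    p <- stats::rnorm(7); a <- stats::rnorm(37)
    balancedResamplingTest(p, a, B = 600, seed = i,
                           null = "absences")@significant
  }, logical(1))
  expect_gt(mean(rej), 0.08)  # nominal would be ~0.05
})

test_that("runAllPredictors tests each column on its own substream", {
  fx <- makeParnassosLike(seed = 706)
  tab <- extractAtPoints(fx$stack, fx$occurrences)
  res <- runAllPredictors(tab, B = 800, seed = 5)
  expect_named(res, c("tri", "tpi", "roughness", "slope", "aspect",
                      "flowdir"))
  expect_identical(unname(vapply(res, function(r) r@predictor, "")),
                   names(res))
  # substream seeds are distinct and recorded
  seeds <- vapply(res, function(r) r@seed, 1L)
  expect_equal(anyDuplicated(seeds), 0L)
  # bit-identical on re-run with the same master seed
  res2 <- runAllPredictors(tab, B = 800, seed = 5)
  for (nm in names(res))
    expect_identical(res[[nm]]@nullMeans, res2[[nm]]@nullMeans)
  # Bonferroni tightens alpha, so the interval can only widen
  resB <- runAllPredictors(tab, B = 800, seed = 5,
                           correction = "bonferroni")
  for (nm in names(res)) {
    expect_lte(resB[[nm]]@ciLow, res[[nm]]@ciLow)
    expect_gte(resB[[nm]]@ciHigh, res[[nm]]@ciHigh)
    expect_equal(resB[[nm]]@alpha, 0.05 / 6)
  }
  expect_error(runAllPredictors(tab[tab$status == 0, , drop = FALSE]),
               "presence")
})

test_that("the circular-aspect mode averages angles on the circle", {
  # angles straddling north: arithmetic mean is ~180, circular mean ~0
  p <- c(350, 10, 355, 5, 358, 2, 352)
  a <- rep(c(350, 10), length.out = 37)
  res <- runAllPredictors(
    data.frame(status = rep(c(1L, 0L), c(7, 37)),
               tri = 1, tpi = 1, roughness = 1, slope = 1,
               aspect = c(p, a), flowdir = 1),
    B = 500, seed = 3, circularAspect = TRUE)
  m <- res$aspect@presenceMean
  expect_true(m < 10 || m > 350)  # near north, not near 180
  expect_match(res$aspect@nullMode, "circular")
})
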