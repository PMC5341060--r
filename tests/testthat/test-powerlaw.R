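test_that("the continuous MLE matches its closed form", {
  f <- fitPowerLaw(exp(1:3), xmin = 1, nCi = 0, minTail = 3)
  expect_equal(f@exponent, 1.5)  # 1 + 3 / (1 + 2 + 3)
  expect_equal(f@nTail, 3L)
})

test_that("the MLE is scale-equivariant", {
  set.seed(51)
  x <- powerlawSamples(2000, 1.8, 1)
  a1 <- fitPowerLaw(x, xmin = 1, nCi = 0)@exponent
  a2 <- fitPowerLaw(x * 1000, xmin = 1000, nCi = 0)@exponent
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("the MLE recovers a known exponent within its asymptotic error", {
  x <- powerlawSamples(1e5, 2, 1, seed = 52)
  f <- fitPowerLaw(x, xmin = 1, nCi = 0)
  se <- (f@exponent - 1) / sqrt(1e5)
  expect_lt(abs(f@exponent - 2), 1.96 * se)
})

test_that("fitting the same data twice is deterministic", {
  x <- powerlawSamples(500, 2.3, 1, seed = 53)
  f1 <- fitPowerLaw(x, seed = 7)
  f2 <- fitPowerLaw(x, seed = 7)
  expect_identical(f1@exponent, f2@exponent)
  expect_identical(f1@xmin, f2@xmin)
  expect_identical(f1@ciHalfwidth, f2@ciHalfwidth)
})

test_that("discrete and continuous MLE agree on far-tail integer data", {
  y <- floor(powerlawSamples(2e4, 2.2, 1000, seed = 54))
  fc <- fitPowerLaw(y, xmin = 1000, nCi = 0)@exponent
  fd <- fitPowerLaw(y, discrete = TRUE, xmin = 1000, nCi = 0)@exponent
  expect_lt(abs(fc - fd), 0.05)
})

test_that("the KS scan finds a lower cutoff near the true onset", {
  set.seed(55)
  # power law above 1, non-power-law bulk below
  x <- c(runif(4000, 0.2, 1), powerlawSamples(6000, 2.5, 1))
  f <- fitPowerLaw(x)
  expect_gt(f@xmin, 0.6)
  expect_lt(f@xmin, 2.5)
  expect_lt(abs(f@exponent - 2.5), 0.15)
})

test_that("degenerate fitting inputs raise domain errors", {
  expect_error(fitPowerLaw(c(-1, 2, 3)), "positive")
  expect_error(fitPowerLaw(rexp(5) + 1, xmin = 1), "insufficient|fewer")
  expect_error(fitPowerLaw(c(1.5, 2.5), discrete = TRUE, xmin = 1,
                           minTail = 2), "integer")
})

test_that("an xmax window excludes an exponential cutoff from the fit", {
  x <- powerlawSamples(5e4, 1.5, 1, seed = 56, cutoff = 1e4)
  full <- fitPowerLaw(x, xmin = 1, nCi = 0)@exponent
  windowed <- fitPowerLaw(x, xmin = 1, xmax = 1e3, nCi = 0)@exponent
  expect_lt(abs(windowed - 1.5), abs(full - 1.5))
  expect_lt(abs(windowed - 1.5), 0.05)
})

test_that("log binning conserves counts and normalizes the density", {
  set.seed(57)
  x <- rexp(5000) + 0.01
  lb <- logBin(x, 1.4)
  expect_equal(sum(lb$counts), 5000)
  expect_equal(sum(lb$density * diff(lb$edges)), 1, tolerance = 1e-9)
  expect_true(all(diff(lb$edges) > 0))
  one <- logBin(rep(2, 10))
  expect_equal(length(one$counts), 1)
  expect_equal(one$density, 1 / diff(one$edges))
  expect_error(logBin(c(-1, 2)), "positive")
  expect_error(logBin(x, 0.9), "ratio")
})

test_that("the log-binned density of a power law has the right slope", {
  x <- powerlawSamples(1e5, 2, 1, seed = 58)
  lb <- logBin(x, 1.3)
  keep <- lb$counts > 20
  slope <- coef(lm(log(lb$density[keep]) ~ log(lb$centers[keep])))[2]
  expect_equal(unname(slope), -2, tolerance = 0.1)
})

test_that("bootstrap p-values keep model data and reject a lognormal", {
  x <- powerlawSamples(2000, 2.5, 1, seed = 59)
  f <- fitPowerLaw(x, xmin = 1, nCi = 0)
  f <- gofPValue(f, x, nBoot = 250, seed = 60)
  expect_gt(f@pValue, 0.05)
  expect_equal(f@nBoot, 250L)
  set.seed(61)
  y <- exp(rnorm(1e4, 1, 0.3))
  fl <- fitPowerLaw(y, xmin = unname(quantile(y, 0.5)), nCi = 0)
  fl <- gofPValue(fl, y, nBoot = 250, seed = 62)
  expect_lt(fl@pValue, 0.05)
  expect_warning(gofPValue(f, x, nBoot = 50, seed = 1), "100")
})
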