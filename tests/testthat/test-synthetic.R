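test_that("power-law samples respect the lower bound and analytic moments", {
  x <- powerlawSamples(1e6, 3, 1, seed = 81)
  expect_true(all(x >= 1))
  # Pareto mean (a-1)/(a-2) = 2 at a = 3
  expect_lt(abs(mean(x) - 2) / 2, 0.01)
})

test_that("the empirical CDF matches the analytic Pareto CDF", {
  n <- 1e5
  x <- sort(powerlawSamples(n, 2.5, 1, seed = 82))
  Fx <- 1 - x^(-1.5)
  D <- max(abs(seq_len(n) / n - Fx))
  expect_lt(D, 1.63 / sqrt(n))
})

test_that("the exponential cutoff suppresses the far tail", {
  x <- powerlawSamples(2e4, 1.5, 1, seed = 83, cutoff = 100)
  expect_lt(quantile(x, 0.999), 2000)
  expect_error(powerlawSamples(10, 1.5, 1, cutoff = 0.5), "infeasible")
})

test_that("discrete draws follow the zeta law closely", {
  k <- powerlawSamples(5e4, 1.77, 1, seed = 84, discrete = TRUE)
  expect_true(all(k == floor(k) & k >= 1))
  f <- fitPowerLaw(k, discrete = TRUE, xmin = 1, nCi = 0)
  expect_lt(abs(f@exponent - 1.77), 0.05)
})

test_that("an empty synthetic signal is pure silence at any threshold", {
  s <- synthVoiceSignal(0, seed = 85)
  ev <- extractEvents(s$energy, thresholdFromEnergy(s$designThreshold))
  expect_equal(nrow(tokens(ev)), 0)
  expect_equal(nrow(s$events), 0)
})

test_that("segmentation at the design threshold recovers the ground truth", {
  s <- synthVoiceSignal(2000, seed = 86)
  ev <- extractEvents(s$energy, thresholdFromEnergy(s$designThreshold))
  expect_equal(nrow(tokens(ev)), nrow(s$events))
  expect_equal(tokens(ev)$startIndex, s$events$startIndex)
  expect_equal(tokens(ev)$lengthSamples, s$events$lengthSamples)
  expect_equal(tokens(ev)$energy, s$events$energy, tolerance = 1e-6)
})

test_that("generators are bit-reproducible given a seed", {
  s1 <- synthVoiceSignal(200, seed = 87)
  s2 <- synthVoiceSignal(200, seed = 87)
  expect_identical(energyValues(s1$energy), energyValues(s2$energy))
  expect_identical(s1$events, s2$events)
  z1 <- zipfStream(1.2, 1e4, seed = 88)
  z2 <- zipfStream(1.2, 1e4, seed = 88)
  expect_identical(typeLabels(z1), typeLabels(z2))
})

test_that("the pipeline recovers the generating energy exponent", {
  s <- synthVoiceSignal(5e4, seed = 89)
  ev <- extractEvents(s$energy, thresholdFromEnergy(s$designThreshold))
  f <- fitPowerLaw(tokens(ev)$energy, xmin = 1, xmax = 1e4, nCi = 0)
  expect_lt(abs(f@exponent - 1.15), 0.05)
  # and the full stream shows Zipf decay plus a decreasing brevity table
  ts <- assignTypes(ev)
  sp <- zipfSpectrum(ts)
  keep <- sp@y > 0 & sp@x <= 30
  slope <- coef(lm(log(sp@y[keep]) ~ log(sp@x[keep])))[2]
  expect_lt(slope, -1)
  bt <- brevityTable(ts)
  expect_lt(cor(bt@x, bt@y, method = "spearman"), 0)
})

test_that("a uniform stream occupies its vocabulary evenly", {
  st <- zipfStream(0, 2e4, vocab = 50, seed = 90)
  freq <- table(typeLabels(st))
  expect_equal(length(freq), 50)
  expect_lt(max(freq) / min(freq), 1.5)
})

test_that("unbounded Zipf streams grow vocabulary as L^(1/z)", {
  st <- zipfStream(1 / 0.91, 1e6, seed = 91)
  hc <- heapsCurve(st)
  fit <- fitHeapsExponent(hc, window = c(100, 1e5))
  expect_lt(abs(fit$alpha - 0.91), 0.05)
})

test_that("finite Zipf streams have rank-frequency slope -z", {
  st <- zipfStream(1, 1e6, vocab = 1e4, seed = 92)
  cnt <- sort(as.numeric(table(typeLabels(st))), decreasing = TRUE)
  r <- seq_along(cnt)
  keep <- r <= 1000
  slope <- coef(lm(log(cnt[keep]) ~ log(r[keep])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.05)
})

test_that("synthetic brevity tables decay at the requested exponent", {
  bc <- brevitySynth(2.9, 1e4, seed = 93)
  expect_equal(sum(bc@y), 1, tolerance = 1e-9)
  expect_lt(cor(bc@x, bc@y, method = "spearman"), 0)
  fit <- fitBrevityExponent(bc)
  expect_lt(abs(fit$beta - 2.9), 0.15)
  expect_error(brevitySynth(0.9, 100), "beta")
})
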