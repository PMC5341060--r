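test_that("the percentile threshold is the stated order statistic", {
  e <- EnergySeries(1:10, 16000)
  t <- resolveThreshold(e, 80)
  expect_equal(resolvedEnergy(t), 3)
  expect_equal(sum(1:10 < resolvedEnergy(t)) / 10, 0.2)
})

test_that("at theta = 80 exactly 20 percent of a continuous series lies strictly below", {
  set.seed(11)
  e <- EnergySeries(runif(1000), 100)
  t <- resolveThreshold(e, 80)
  expect_equal(mean(energyValues(e) < resolvedEnergy(t)), 0.2)
})

test_that("theta near 100 resolves to the minimum with nothing below", {
  set.seed(12)
  e <- EnergySeries(runif(1000), 100)
  t <- resolveThreshold(e, 99.99)
  expect_equal(resolvedEnergy(t), min(energyValues(e)))
  expect_equal(sum(energyValues(e) < resolvedEnergy(t)), 0)
})

test_that("constant series and out-of-range theta are rejected", {
  e <- EnergySeries(rep(2, 100), 100)
  expect_error(resolveThreshold(e, 80), "degenerate")
  e2 <- EnergySeries(runif(10), 100)
  expect_error(resolveThreshold(e2, 0), "in \\(0, 100\\)")
  expect_error(resolveThreshold(e2, 100), "in \\(0, 100\\)")
})

test_that("raising theta never increases the resolved energy", {
  set.seed(13)
  for (i in 1:5) {
    e <- EnergySeries(rexp(500)^2, 100)
    res <- vapply(c(10, 30, 50, 70, 90, 99),
                  function(th) resolvedEnergy(resolveThreshold(e, th)), 0)
    expect_true(all(diff(res) <= 0))
  }
})

test_that("a hand-countable series segments into the expected runs", {
  e <- EnergySeries(c(0, 5, 5, 0), 100)
  ev <- extractEvents(e, thresholdFromEnergy(1))
  expect_equal(nrow(tokens(ev)), 1)
  expect_equal(tokens(ev)$startIndex, 1)
  expect_equal(tokens(ev)$lengthSamples, 2)
  expect_equal(tokens(ev)$energy, 10)
  expect_equal(silences(ev)$lengthSamples, c(1, 1))
})

test_that("all samples above threshold give one token and no silence", {
  e <- EnergySeries(rep(5, 20), 100)
  ev <- extractEvents(e, thresholdFromEnergy(1))
  expect_equal(nrow(tokens(ev)), 1)
  expect_equal(tokens(ev)$lengthSamples, 20)
  expect_equal(nrow(silences(ev)), 0)
})

test_that("zero tokens is a legal outcome", {
  e <- EnergySeries(runif(100, 0, 0.5), 100)
  ev <- extractEvents(e, thresholdFromEnergy(1))
  expect_equal(nrow(tokens(ev)), 0)
  expect_equal(nrow(silences(ev)), 1)
})

test_that("segmentation matches a naive per-sample run scan on random data", {
  set.seed(14)
  v <- rexp(10000)
  e <- EnergySeries(v, 16000)
  t <- resolveThreshold(e, 70)
  ev <- extractEvents(e, t)
  oracle <- naiveRunScan(v, resolvedEnergy(t))
  expect_equal(nrow(tokens(ev)), length(oracle$tokens))
  expect_equal(tokens(ev)$startIndex,
               vapply(oracle$tokens, `[[`, 0, "start"))
  expect_equal(tokens(ev)$lengthSamples,
               vapply(oracle$tokens, `[[`, 0, "len"))
  expect_equal(tokens(ev)$energy,
               vapply(oracle$tokens, `[[`, 0, "energy"),
               tolerance = 1e-12)
  expect_equal(silences(ev)$startIndex,
               vapply(oracle$silences, `[[`, 0, "start"))
})

test_that("token energies conserve the total above-threshold energy", {
  set.seed(15)
  v <- rexp(5000)^2
  e <- EnergySeries(v, 100)
  t <- resolveThreshold(e, 60)
  ev <- extractEvents(e, t)
  thr <- resolvedEnergy(t)
  expect_equal(sum(tokens(ev)$energy), sum(v[v > thr]), tolerance = 1e-9)
  expect_equal(sum(tokens(ev)$energy) + sum(v[v <= thr]), sum(v),
               tolerance = 1e-9)
})

test_that("tokens and silences tile the series under the keep policy", {
  set.seed(16)
  v <- runif(3000)
  ev <- extractEvents(EnergySeries(v, 100), thresholdFromEnergy(0.4))
  expect_equal(sum(tokens(ev)$lengthSamples) +
                 sum(silences(ev)$lengthSamples), 3000)
  runs <- data.frame(
    start = c(tokens(ev)$startIndex, silences(ev)$startIndex),
    len = c(tokens(ev)$lengthSamples, silences(ev)$lengthSamples))
  runs <- runs[order(runs$start), ]
  expect_equal(runs$start[-1], head(runs$start + runs$len, -1))  # contiguous
})

test_that("concatenation across a silent gap unions the token sets", {
  set.seed(17)
  a <- runif(500); b <- runif(400)
  thr <- thresholdFromEnergy(0.5)
  ta <- tokens(extractEvents(EnergySeries(a, 1), thr))
  tb <- tokens(extractEvents(EnergySeries(b, 1), thr))
  tb$startIndex <- tb$startIndex + 510
  tc <- tokens(extractEvents(EnergySeries(c(a, rep(0.1, 10), b), 1), thr))
  joined <- rbind(ta, tb)
  rownames(joined) <- rownames(tc) <- NULL
  expect_equal(tc, joined)
})

test_that("the drop policy removes edge runs but records their count", {
  e <- EnergySeries(c(5, 0, 5, 0, 5), 100)  # token runs touch both edges
  keep <- extractEvents(e, thresholdFromEnergy(1), "keep")
  drop <- extractEvents(e, thresholdFromEnergy(1), "drop")
  expect_equal(nrow(tokens(keep)), 3)
  expect_equal(nrow(tokens(drop)), 1)
  expect_equal(drop@droppedTokens, 2L)
  expect_equal(nrow(silences(drop)), 2)
})

test_that("the event table interleaves tokens and silences in order", {
  e <- EnergySeries(c(0, 5, 0, 5, 5), 100)
  ev <- extractEvents(e, resolveThreshold(e, 60))
  tab <- eventTable(ev)
  expect_equal(nrow(tab), nrow(tokens(ev)) + nrow(silences(ev)))
  expect_true(!is.unsorted(tab$startIndex))
  expect_true(all(c("kind", "thetaPercent") %in% names(tab)))
})
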