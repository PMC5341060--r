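test_that("the Zipf spectrum counts types by occurrence number", {
  sp <- zipfSpectrum(TypeSequence(c(7, 9, 7)))  # {a, b, a}
  expect_equal(sp@x, c(1, 2))
  expect_equal(sp@y, c(1, 1))
  one <- zipfSpectrum(TypeSequence(rep(3, 12)))
  expect_equal(one@x, 12)
  expect_equal(one@y, 1)
})

test_that("the spectrum matches a brute-force counter of counters", {
  set.seed(31)
  labels <- sample.int(50, 1000, replace = TRUE)
  sp <- zipfSpectrum(TypeSequence(labels))
  perType <- table(labels)
  oracle <- table(as.numeric(perType))
  expect_equal(sp@x, as.numeric(names(oracle)))
  expect_equal(sp@y, as.numeric(oracle))
})

test_that("Zipf sum rules hold exactly for arbitrary streams", {
  set.seed(32)
  for (i in 1:5) {
    labels <- sample.int(sample(2:200, 1), sample(10:2000, 1),
                         replace = TRUE)
    ts <- TypeSequence(labels)
    sp <- zipfSpectrum(ts)
    expect_identical(sum(sp@y), as.numeric(vocabularyStats(ts)$V))
    expect_identical(sum(sp@x * sp@y), as.numeric(length(labels)))
  }
})

test_that("the Heaps curve is the running count of distinct types", {
  hc <- heapsCurve(TypeSequence(c(0, 1, 0, 2, 1, 0)))
  expect_equal(hc@y, c(1, 2, 2, 3, 3, 3))
  expect_equal(hc@x, 1:6)
  set.seed(33)
  labels <- sample.int(30, 500, replace = TRUE)
  hc2 <- heapsCurve(TypeSequence(labels))
  oracle <- vapply(seq_along(labels),
                   function(k) length(unique(labels[seq_len(k)])), 0)
  expect_equal(hc2@y, oracle)
  expect_true(all(diff(hc2@y) %in% c(0, 1)))
  expect_equal(max(hc2@y), vocabularyStats(TypeSequence(labels))$V)
})

test_that("degenerate streams give Heaps slope 0 and 1", {
  const <- heapsCurve(TypeSequence(rep(1, 300)))
  expect_equal(fitHeapsExponent(const)$alpha, 0)
  distinct <- heapsCurve(TypeSequence(1:300))
  expect_equal(fitHeapsExponent(distinct)$alpha, 1, tolerance = 1e-10)
})

test_that("the brevity table averages durations within each type", {
  ts <- TypeSequence(c(1, 1), durations = c(2, 4))
  bt <- brevityTable(ts)
  expect_equal(bt@x, 3)
  expect_equal(bt@y, 1)
  ts2 <- TypeSequence(c(1, 1, 1, 2), durations = c(1, 1, 1, 10))
  bt2 <- brevityTable(ts2)
  expect_equal(bt2@x, c(1, 10))
  expect_equal(bt2@y, c(0.75, 0.25))
  expect_true(all(diff(bt2@y) < 0))
})

test_that("brevity means match an explicit group-by oracle", {
  set.seed(34)
  labels <- sample.int(20, 400, replace = TRUE)
  dur <- rexp(400)
  bt <- brevityTable(TypeSequence(labels, durations = dur))
  oracleMean <- tapply(dur, labels, mean)
  oracleFreq <- as.numeric(table(labels)) / 400
  o <- order(oracleMean)
  expect_equal(bt@x, as.numeric(oracleMean)[o])
  expect_equal(bt@y, oracleFreq[o])
  expect_equal(sum(bt@y), 1, tolerance = 1e-9)
})

test_that("a single curve self-collapses with zero overlap score", {
  sp <- zipfSpectrum(TypeSequence(c(1, 1, 2, 3, 3, 3)))
  cc <- collapseCurves(sp)
  expect_equal(cc$overlapScore, 0)
  expect_length(cc$curves[[1]]@xRescaled, length(sp@x))
})

test_that("identical curves collapse to zero and the score is order-invariant", {
  set.seed(35)
  labels <- sample.int(40, 800, replace = TRUE, prob = 1 / (1:40))
  c1 <- zipfSpectrum(TypeSequence(labels))
  c2 <- zipfSpectrum(TypeSequence(rev(labels)))
  expect_equal(collapseCurves(list(c1, c1))$overlapScore, 0)
  s12 <- collapseCurves(list(c1, c2))$overlapScore
  s21 <- collapseCurves(list(c2, c1))$overlapScore
  expect_equal(s12, s21)
  expect_error(collapseCurves(list(c1, heapsCurve(TypeSequence(1:5)))),
               "one lawId")
})

test_that("exact power-law curves with different cutoffs moment-collapse", {
  mkcurve <- function(xi, phi = 1.5, n = 4000) {
    x <- exp(seq(log(1), log(xi * 5), length.out = n))
    y <- x^(-phi) * exp(-x / xi)
    tz <- function(f) sum(diff(x) * (head(f, -1) + tail(f, -1)) / 2)
    yn <- y / tz(y)
    LawCurve("energy", x, yn,
             moments = list(meanE = tz(x * yn), meanE2 = tz(x^2 * yn)))
  }
  cc <- collapseCurves(list(mkcurve(1e4), mkcurve(1e6)))
  expect_lt(cc$overlapScore, 1e-2)
})

test_that("Zipf collapse preserves the sum rules in rescaled form", {
  set.seed(36)
  labels <- sample.int(60, 1200, replace = TRUE, prob = 1 / (1:60)^1.2)
  sp <- zipfSpectrum(TypeSequence(labels))
  cc <- collapseCurves(sp)$curves[[1]]
  V <- sp@moments$V; L <- sp@moments$L
  expect_equal(sum(cc@yRescaled), 1)              # sum N(n)/V = 1
  expect_equal(sum(cc@xRescaled * cc@yRescaled), 1)  # sum n V / (L V) = 1
})

test_that("energy density integrates to one and records its moments", {
  ev <- eventSeqFromTokens(rexp(2000) + 0.1)
  cv <- energyDistribution(ev)
  E <- ev@tokens$energy
  expect_equal(cv@moments$meanE, mean(E))
  expect_equal(cv@moments$meanE2, mean(E^2))
  expect_error(energyDistribution(eventSeqFromTokens(5)), "degenerate")
  same <- energyDistribution(eventSeqFromTokens(rep(2, 5)))
  expect_equal(length(same@x), 1)
})

test_that("exponent relations reproduce the stated identities", {
  er <- exponentRelations(alpha = 0.91)
  expect_equal(round(er$alphaPrime, 2), 0.48)
  expect_equal(exponentRelations(z = 1)$zeta, 2)
  expect_equal(exponentRelations(phi = 1.15)$zetaPred, 1 + 1 / 1.15)
  expect_equal(exponentRelations(zeta = 1.8)$z, 1 / 0.8)
  expect_equal(exponentRelations(zeta = 1.8)$alpha, 0.8)
})

test_that("derived exponent maps are involutive to 1e-12", {
  for (a in c(0.3, 0.91, 0.99)) {
    ap <- exponentRelations(alpha = a)$alphaPrime
    back <- exponentRelations(alphaPrime = ap)$alpha
    expect_equal(back, a, tolerance = 1e-12)
  }
  z <- exponentRelations(zeta = 1.77)$z
  expect_equal(exponentRelations(z = z)$zeta, 1.77, tolerance = 1e-12)
})

test_that("out-of-domain exponents are rejected", {
  expect_error(exponentRelations(z = -1), "z must be")
  expect_error(exponentRelations(alphaPrime = 1.2), "alphaPrime")
})
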