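## Seedable generators with known ground-truth exponents. These define the
## package's reference study conditions: every stage of the pipeline is
## testable against them without external data.

#' Draw samples from a (possibly cutoff) continuous power law
#'
#' Inverse-CDF sampling of the Pareto density \eqn{p(x) \propto x^{-a}},
#' \eqn{x \ge x_{min}}; `u = 0` maps to `xmin`. An optional exponential
#' cutoff at scale `cutoff` is applied by rejection, yielding \eqn{p(x)
#' \propto x^{-a} e^{-x/\xi}}.
#'
#' @param n number of samples.
#' @param exponent power-law exponent \eqn{a > 1}.
#' @param xmin lower bound (> 0).
#' @param seed RNG seed (`NULL` continues the current RNG stream).
#' @param cutoff exponential cutoff scale \eqn{\xi} (`NULL` for none; must
#'   exceed `xmin`; continuous only).
#' @param discrete draw from the discrete (zeta) law \eqn{P(k) \propto
#'   k^{-a}}, \eqn{k \ge x_{min}} integer, by exact inversion.
#' @return numeric vector of `n` positive samples.
#' @export
powerlawSamples <- function(n, exponent, xmin = 1, seed = NULL,
                            cutoff = NULL, discrete = FALSE) {
  stopifnot(n >= 1, exponent > 1, xmin > 0)
  if (!is.null(cutoff) && cutoff <= xmin)
    stop("infeasible: cutoff scale must exceed xmin")
  if (!is.null(seed)) set.seed(seed)
  if (discrete) {
    if (!is.null(cutoff)) stop("cutoff is not supported for discrete draws")
    return(.rzeta(n, exponent, as.integer(xmin)))
  }
  if (is.null(cutoff)) return(.rpareto(n, exponent, xmin))
  out <- numeric(0)
  # acceptance rate ~ E[exp(-x/cutoff)], close to 1 when xmin << cutoff
  while (length(out) < n) {
    m <- max(1000, 2 * (n - length(out)))
    x <- .rpareto(m, exponent, xmin)
    out <- c(out, x[runif(m) < exp(-x / cutoff)])
  }
  out[seq_len(n)]
}

#' Synthesize a voice-like energy signal with known event structure
#'
#' Builds an instantaneous-energy series \eqn{\epsilon(t)} as an
#' alternation of silence gaps and voice events, emulating the avalanche
#' structure the thresholding method assumes: gap durations follow a power
#' law; event energies follow a power law of exponent `phiTrue` with an
#' exponential cutoff; event durations scale with energy as \eqn{T \propto
#' E^{1/d}} (so longer events carry more energy — the brevity-compatible
#' geometry); within an event the energy is spread as a raised-cosine bump
#' riding on a pedestal that keeps every event sample above the design
#' threshold. Silence samples are uniform below `floorLevel`.
#'
#' @param eventCount number of voice events (0 gives pure silence).
#' @param phiTrue target energy exponent (> 1); default 1.15.
#' @param cutoffScale exponential cutoff of event energies; default 1e5
#'   (five decades of scaling range, as in wide-band speech).
#' @param xminEnergy lower bound of event energies; default 1. With the
#'   default type bin width 0.01 the low-energy bins then agglutinate many
#'   tokens each (about 30 tokens per 20000 in the first bin), giving a
#'   nontrivial vocabulary.
#' @param silenceExponent power-law exponent of gap durations; default 2.
#' @param silenceMinSamples shortest gap, in samples; default 16 (1 ms at
#'   16 kHz).
#' @param silenceCutoff exponential cutoff of gap durations, in samples.
#' @param durationCoupling exponent \eqn{d} in \eqn{T \propto E^{1/d}};
#'   default 2.
#' @param durationScale samples per unit \eqn{E^{1/d}}; default 8
#'   (typical events a few ms, the largest ~0.16 s at 16 kHz; a
#'   voice-activity fraction around 55\%).
#' @param rate sampling rate in Hz; default 16000.
#' @param floorLevel upper bound of silence sample values; default 1e-4.
#' @param pedestal per-sample energy floor inside events (> `floorLevel`);
#'   default 2e-4.
#' @param seed RNG seed.
#' @return list with `energy` (an [EnergySeries-class]), `events` (ground
#'   truth data.frame: `startIndex` 0-based, `lengthSamples`, `energy`),
#'   `designThreshold` (an energy value between floor and pedestal at which
#'   segmentation recovers the ground truth exactly), and `spec` (echo of
#'   all parameters).
#' @export
synthVoiceSignal <- function(eventCount, phiTrue = 1.15, cutoffScale = 1e5,
                             xminEnergy = 1, silenceExponent = 2,
                             silenceMinSamples = 16, silenceCutoff = 1e5,
                             durationCoupling = 2, durationScale = 8,
                             rate = 16000, floorLevel = 1e-4,
                             pedestal = 2e-4, seed = 1) {
  stopifnot(eventCount >= 0, phiTrue > 1, pedestal > floorLevel)
  if (cutoffScale <= xminEnergy)
    stop("infeasible: cutoffScale must exceed xminEnergy")
  set.seed(seed)
  spec <- list(eventCount = eventCount, phiTrue = phiTrue,
               cutoffScale = cutoffScale, xminEnergy = xminEnergy,
               silenceExponent = silenceExponent,
               silenceMinSamples = silenceMinSamples,
               silenceCutoff = silenceCutoff,
               durationCoupling = durationCoupling,
               durationScale = durationScale, rate = rate,
               floorLevel = floorLevel, pedestal = pedestal, seed = seed)
  nGaps <- eventCount + 1
  gaps <- round(powerlawSamples(nGaps, silenceExponent, silenceMinSamples,
                                cutoff = silenceCutoff))
  if (eventCount == 0) {
    values <- runif(gaps[1], 0, floorLevel)
    return(list(energy = EnergySeries(values, rate, "synthetic voice (empty)"),
                events = data.frame(startIndex = integer(0),
                                    lengthSamples = integer(0),
                                    energy = numeric(0)),
                designThreshold = (floorLevel + pedestal) / 2, spec = spec))
  }
  E <- powerlawSamples(eventCount, phiTrue, xminEnergy, cutoff = cutoffScale)
  T <- pmax(1, round(durationScale * E^(1 / durationCoupling)))
  # keep the pedestal affordable: at most half the event energy
  T <- pmin(T, pmax(1, floor(E / (2 * pedestal))))
  N <- sum(gaps) + sum(T)
  values <- runif(N, 0, floorLevel)
  starts <- cumsum(c(0, T[-eventCount])) + cumsum(gaps[-nGaps])  # 0-based
  for (i in seq_len(eventCount)) {
    Ti <- T[i]
    w <- (1 - cos(2 * pi * seq_len(Ti) / (Ti + 1))) / 2
    w <- w / sum(w)
    values[(starts[i] + 1):(starts[i] + Ti)] <-
      pedestal + (E[i] - Ti * pedestal) * w
  }
  list(energy = EnergySeries(values, rate, "synthetic voice"),
       events = data.frame(startIndex = starts, lengthSamples = T,
                           energy = E),
       designThreshold = (floorLevel + pedestal) / 2, spec = spec)
}

#' Generate an i.i.d. Zipf-distributed token stream
#'
#' Draws `L` tokens with rank probabilities \eqn{p(r) \propto r^{-z}}. A
#' finite vocabulary samples the exact rank distribution; an unbounded
#' vocabulary (`vocab = Inf`) uses a rank distribution truncated at a
#' machine-feasible maximum rank (1e8) with mass renormalized, realized as
#' the floor of a truncated continuous power law so that \eqn{p(r) =
#' \int_r^{r+1} x^{-z} dx \sim r^{-z}}.
#'
#' @param z rank exponent (>= 0).
#' @param L stream length (number of tokens).
#' @param vocab vocabulary size, or `Inf` for unbounded.
#' @param seed RNG seed.
#' @param maxRank truncation rank for the unbounded case; default 1e8.
#' @return a [TypeSequence-class] of `L` labels.
#' @export
zipfStream <- function(z, L, vocab = Inf, seed = 1, maxRank = 1e8) {
  stopifnot(z >= 0, L >= 1)
  set.seed(seed)
  if (is.finite(vocab)) {
    p <- seq_len(vocab)^(-z)
    labels <- sample.int(vocab, L, replace = TRUE, prob = p)
  } else {
    R <- maxRank + 1
    u <- runif(L)
    x <- if (abs(z - 1) < 1e-12) R^u
         else (1 + u * (R^(1 - z) - 1))^(1 / (1 - z))
    labels <- floor(x)
  }
  TypeSequence(labels)
}

#' Synthesize a brevity table with a known decay exponent
#'
#' Type mean-durations are drawn from a power law; relative frequencies are
#' assigned proportional to \eqn{t^{-\beta}} and normalized, so the table
#' decays with the exact exponent `beta` and is monotonically decreasing in
#' duration.
#'
#' @param beta decay exponent (> 1).
#' @param nTypes number of types.
#' @param seed RNG seed.
#' @param durationExponent power-law exponent of the duration draw;
#'   default 2.
#' @param xminDuration shortest mean duration, seconds; default 0.01.
#' @return a `"brevity"` [LawCurve-class]; frequencies sum to 1.
#' @export
brevitySynth <- function(beta, nTypes, seed = 1, durationExponent = 2,
                         xminDuration = 0.01) {
  stopifnot(beta > 1, nTypes >= 2)
  t <- sort(unique(powerlawSamples(nTypes, durationExponent, xminDuration,
                                   seed = seed)))
  f <- t^(-beta)
  f <- f / sum(f)
  LawCurve("brevity", t, f,
           moments = list(meanDuration = sum(t * f), L = NA_real_))
}
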