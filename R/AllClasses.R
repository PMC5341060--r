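#' @import methods
#' @importFrom stats optimize runif quantile approx sd median lm coef
#' @importFrom utils combn head tail read.table write.csv
NULL

.LAW_IDS <- c("energy", "zipf", "heaps", "brevity")

#' AmplitudeSeries: a sampled acoustic waveform
#'
#' Container for a mono amplitude time series \eqn{A(t)}, dimensionless and
#' (by default) normalized to \eqn{[-1, 1]} by the full scale of the source
#' integer encoding.
#'
#' @slot samples numeric amplitude per time step.
#' @slot rate sampling rate in Hz.
#' @slot sourceLabel free-text provenance.
#' @slot normalized whether samples were scaled to full-scale \eqn{[-1,1]}.
#' @exportClass AmplitudeSeries
setClass("AmplitudeSeries",
  representation(samples = "numeric", rate = "numeric",
                 sourceLabel = "character", normalized = "logical"),
  prototype(samples = numeric(0), rate = 16000,
            sourceLabel = "", normalized = TRUE))

setValidity("AmplitudeSeries", function(object) {
  msg <- character(0)
  if (length(object@rate) != 1 || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (isTRUE(object@normalized) && length(object@samples) &&
      max(abs(object@samples)) > 1 + 1e-12)
    msg <- c(msg, "normalized samples must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' EnergySeries: instantaneous energy per time step
#'
#' Container for \eqn{\epsilon(t) = |A(t)|^2}, the semi-definite positive
#' instantaneous energy of a signal (amplitude-squared units, constants
#' dropped). This is the object the thresholding method operates on.
#'
#' @slot values nonnegative energy per time step.
#' @slot rate sampling rate in Hz.
#' @slot sourceLabel free-text provenance.
#' @exportClass EnergySeries
setClass("EnergySeries",
  representation(values = "numeric", rate = "numeric",
                 sourceLabel = "character"),
  prototype(values = numeric(0), rate = 16000, sourceLabel = ""))

setValidity("EnergySeries", function(object) {
  msg <- character(0)
  if (length(object@values) == 0)
    msg <- c(msg, "an EnergySeries must contain at least one value")
  if (length(object@rate) != 1 || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(object@values) &&
      (!all(is.finite(object@values)) || any(object@values < 0)))
    msg <- c(msg, "all energy values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' ThresholdSpec: a percentile energy threshold
#'
#' The threshold \eqn{\Theta} is declared as the percentage of samples that
#' remain at or above the resolved energy level: \eqn{\Theta = 80\%} means
#' 20\% of the samples fall strictly below `resolvedEnergy`.
#'
#' @slot thetaPercent percentage of samples kept at/above threshold, in
#'   (0, 100); `NA` when the threshold was given directly in energy units.
#' @slot resolvedEnergy the threshold in energy units.
#' @exportClass ThresholdSpec
setClass("ThresholdSpec",
  representation(thetaPercent = "numeric", resolvedEnergy = "numeric"),
  prototype(thetaPercent = NA_real_, resolvedEnergy = NA_real_))

setValidity("ThresholdSpec", function(object) {
  tp <- object@thetaPercent
  if (length(tp) != 1 || (!is.na(tp) && (tp <= 0 || tp >= 100)))
    return("thetaPercent must be a single value in (0, 100) or NA")
  TRUE
})

#' EventSequence: tokens and silences of a thresholded energy series
#'
#' Result of cutting an energy series at a threshold: maximal runs of
#' samples strictly above the threshold are voice events (tokens), each
#' characterized by the duple (integrated energy \eqn{E_v}, duration
#' \eqn{T_v}); maximal runs at/below threshold are silence gaps of duration
#' \eqn{\tau}. Tokens and silences tile the series without overlap.
#'
#' @slot threshold the [ThresholdSpec-class] used.
#' @slot tokens data.frame with columns `startIndex` (0-based),
#'   `lengthSamples`, `durationS`, `energy`.
#' @slot silences data.frame with columns `startIndex`, `lengthSamples`,
#'   `durationS`.
#' @slot seriesLength total number of samples in the series.
#' @slot rate sampling rate in Hz.
#' @slot boundaryPolicy `"keep"` or `"drop"` (edge-touching runs dropped
#'   from statistics).
#' @slot droppedTokens,droppedSilences counts of edge runs removed under
#'   the drop policy.
#' @exportClass EventSequence
setClass("EventSequence",
  representation(threshold = "ThresholdSpec", tokens = "data.frame",
                 silences = "data.frame", seriesLength = "numeric",
                 rate = "numeric", boundaryPolicy = "character",
                 droppedTokens = "integer", droppedSilences = "integer"),
  prototype(seriesLength = 0, rate = 16000, boundaryPolicy = "keep",
            droppedTokens = 0L, droppedSilences = 0L))

setValidity("EventSequence", function(object) {
  msg <- character(0)
  need <- c("startIndex", "lengthSamples", "durationS", "energy")
  if (!all(need %in% names(object@tokens)))
    msg <- c(msg, paste("tokens must have columns:", paste(need, collapse = ", ")))
  if (!all(c("startIndex", "lengthSamples", "durationS") %in% names(object@silences)))
    msg <- c(msg, "silences must have columns startIndex, lengthSamples, durationS")
  if (nrow(object@tokens)) {
    if (any(object@tokens$energy <= 0)) msg <- c(msg, "token energies must be > 0")
    if (any(object@tokens$lengthSamples <= 0)) msg <- c(msg, "token lengths must be > 0")
  }
  if (!object@boundaryPolicy %in% c("keep", "drop"))
    msg <- c(msg, "boundaryPolicy must be 'keep' or 'drop'")
  if (length(msg)) msg else TRUE
})

#' TypeSequence: symbolized token stream
#'
#' Ordered energy-bin labels (types) for the tokens of an [EventSequence-class],
#' obtained by linear binning of integrated energies: tokens whose energies
#' fall in the same bin share a type even if their durations differ. Carries
#' the vocabulary bookkeeping: number of types \eqn{V}, number of tokens
#' \eqn{L}.
#'
#' @slot labels ordered nonnegative integer bin index per token.
#' @slot binWidth bin size \eqn{b} in energy units (`NA` for streams that
#'   were generated symbolically rather than binned).
#' @slot origin bin origin \eqn{E_0} in energy units.
#' @slot energies token energies aligned with `labels` (may be empty for
#'   symbolic streams).
#' @slot durations token durations in seconds aligned with `labels` (may be
#'   empty).
#' @exportClass TypeSequence
setClass("TypeSequence",
  representation(labels = "numeric", binWidth = "numeric", origin = "numeric",
                 energies = "numeric", durations = "numeric"),
  prototype(binWidth = NA_real_, origin = NA_real_,
            energies = numeric(0), durations = numeric(0)))

setValidity("TypeSequence", function(object) {
  msg <- character(0)
  if (length(object@labels) == 0)
    msg <- c(msg, "a TypeSequence must contain at least one label")
  if (length(object@labels) && any(object@labels < 0))
    msg <- c(msg, "labels must be >= 0")
  for (s in c("energies", "durations")) {
    v <- slot(object, s)
    if (length(v) && length(v) != length(object@labels))
      msg <- c(msg, paste(s, "must be empty or aligned with labels"))
  }
  if (length(msg)) msg else TRUE
})

#' LawCurve: one empirical law at one threshold
#'
#' A single empirical curve — energy-release distribution \eqn{P_\Theta(E)},
#' Zipf frequency spectrum \eqn{N_\Theta(n)}, Heaps vocabulary-growth curve
#' \eqn{V(L)}, or brevity table \eqn{M_\Theta(t)} — together with its
#' collapse-rescaled coordinates and the moments needed for the rescaling.
#'
#' @slot lawId one of `"energy"`, `"zipf"`, `"heaps"`, `"brevity"`.
#' @slot thetaPercent threshold the curve was measured at (`NA` if not
#'   applicable).
#' @slot x,y abscissa and ordinate.
#' @slot xRescaled,yRescaled collapse coordinates (filled by
#'   [collapseCurves()]; `NA` before).
#' @slot moments named list of rescaling quantities (e.g. `meanE`, `meanE2`
#'   for the energy law; `V`, `L` for Zipf; `meanDuration` for brevity).
#' @exportClass LawCurve
setClass("LawCurve",
  representation(lawId = "character", thetaPercent = "numeric",
                 x = "numeric", y = "numeric",
                 xRescaled = "numeric", yRescaled = "numeric",
                 moments = "list"),
  prototype(thetaPercent = NA_real_, xRescaled = numeric(0),
            yRescaled = numeric(0), moments = list()))

setValidity("LawCurve", function(object) {
  msg <- character(0)
  if (!object@lawId %in% .LAW_IDS)
    msg <- c(msg, paste("lawId must be one of:", paste(.LAW_IDS, collapse = ", ")))
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have equal length")
  if (length(object@x) > 1 && any(diff(object@x) <= 0))
    msg <- c(msg, "x must be strictly increasing")
  if (length(object@y) && any(object@y < 0))
    msg <- c(msg, "y must be >= 0")
  if (length(object@xRescaled) &&
      length(object@xRescaled) != length(object@x))
    msg <- c(msg, "rescaled coordinates must match the originals in length")
  if (length(msg)) msg else TRUE
})

#' PowerLawFit: maximum-likelihood power-law fit
#'
#' Result of fitting \eqn{p(x) \propto x^{-\hat\alpha}} for \eqn{x \ge
#' x_{min}} by MLE, with Kolmogorov-Smirnov goodness of fit and (optionally)
#' a parametric-bootstrap p-value in the Clauset convention.
#'
#' @slot exponent fitted exponent, > 1.
#' @slot xmin lower cutoff above which the law is fitted.
#' @slot xmax optional upper fit limit (`Inf` if unused); used to exclude an
#'   exponential cutoff region.
#' @slot ksStat KS distance between tail data and the fitted model.
#' @slot pValue bootstrap p-value (`NA` until [gofPValue()] is run).
#' @slot ciHalfwidth bootstrap confidence half-width of the exponent.
#' @slot nTail number of samples in the fitted tail.
#' @slot nBoot bootstrap replicates used for the p-value (0 if none).
#' @slot discrete whether the zeta-function (discrete) likelihood was used.
#' @slot seed RNG seed recorded for the stochastic parts (`NA` if none run).
#' @exportClass PowerLawFit
setClass("PowerLawFit",
  representation(exponent = "numeric", xmin = "numeric", xmax = "numeric",
                 ksStat = "numeric", pValue = "numeric",
                 ciHalfwidth = "numeric", nTail = "integer",
                 nBoot = "integer", discrete = "logical", seed = "numeric"),
  prototype(xmax = Inf, pValue = NA_real_, ciHalfwidth = NA_real_,
            nBoot = 0L, discrete = FALSE, seed = NA_real_))

setValidity("PowerLawFit", function(object) {
  msg <- character(0)
  if (length(object@exponent) != 1 || !is.finite(object@exponent) ||
      object@exponent <= 1)
    msg <- c(msg, "exponent must be a single finite value > 1")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must be in [0, 1]")
  if (is.finite(object@ksStat) && object@ksStat < 0)
    msg <- c(msg, "ksStat must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "AmplitudeSeries", function(object) {
  cat(sprintf("AmplitudeSeries: %d samples @ %g Hz (%.3f s)%s\n",
              length(object@samples), object@rate,
              length(object@samples) / object@rate,
              if (nzchar(object@sourceLabel))
                paste0(" [", object@sourceLabel, "]") else ""))
})

setMethod("show", "EnergySeries", function(object) {
  cat(sprintf("EnergySeries: %d samples @ %g Hz, total energy %.4g%s\n",
              length(object@values), object@rate, sum(object@values),
              if (nzchar(object@sourceLabel))
                paste0(" [", object@sourceLabel, "]") else ""))
})

setMethod("show", "ThresholdSpec", function(object) {
  cat(sprintf("ThresholdSpec: theta = %s%%, resolved energy = %.6g\n",
              format(object@thetaPercent), object@resolvedEnergy))
})

setMethod("show", "EventSequence", function(object) {
  cat(sprintf(
    "EventSequence: %d tokens, %d silences over %d samples (theta = %s%%, policy = %s)\n",
    nrow(object@tokens), nrow(object@silences), object@seriesLength,
    format(object@threshold@thetaPercent), object@boundaryPolicy))
})

setMethod("show", "TypeSequence", function(object) {
  cat(sprintf("TypeSequence: L = %d tokens, V = %d types (b = %s)\n",
              length(object@labels), length(unique(object@labels)),
              format(object@binWidth)))
})

setMethod("show", "LawCurve", function(object) {
  cat(sprintf("LawCurve <%s>: %d points%s%s\n", object@lawId,
              length(object@x),
              if (!is.na(object@thetaPercent))
                sprintf(", theta = %g%%", object@thetaPercent) else "",
              if (length(object@xRescaled)) ", collapsed" else ""))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit (%s): exponent = %.4f, xmin = %.4g, n_tail = %d, KS = %.4g%s\n",
    if (object@discrete) "discrete" else "continuous",
    object@exponent, object@xmin, object@nTail, object@ksStat,
    if (!is.na(object@pValue))
      sprintf(", p = %.3f (%d reps)", object@pValue, object@nBoot) else ""))
})
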