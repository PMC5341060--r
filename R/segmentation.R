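#' Resolve a percentile threshold into an energy value
#'
#' The threshold \eqn{\Theta} is a percentage of the signal kept at or above
#' the threshold: \eqn{\Theta = 80\%} means 20\% of the samples fall under
#' the resolved energy level. The resolved value is the order statistic of
#' rank `floor(q * N) + 1` with `q = (100 - thetaPercent) / 100`, so the
#' fraction of samples strictly below it is as close to `q` as ties permit
#' and never exceeds `q`.
#'
#' @param e an [EnergySeries-class].
#' @param thetaPercent percentage in (0, 100).
#' @return a [ThresholdSpec-class] with `resolvedEnergy` filled.
#' @export
resolveThreshold <- function(e, thetaPercent) {
  stopifnot(is(e, "EnergySeries"))
  if (!is.numeric(thetaPercent) || length(thetaPercent) != 1 ||
      thetaPercent <= 0 || thetaPercent >= 100)
    stop("thetaPercent must be a single value in (0, 100)")
  v <- e@values
  if (max(v) == min(v))
    stop("degenerate threshold: the energy series is constant (all values tied)")
  q <- (100 - thetaPercent) / 100
  k <- floor(q * length(v)) + 1
  resolved <- sort(v, partial = k)[k]
  new("ThresholdSpec", thetaPercent = thetaPercent,
      resolvedEnergy = resolved)
}

#' Declare a threshold directly in energy units
#'
#' Bypasses the percentile convention; useful when a design threshold is
#' known (e.g. from a synthetic generator).
#'
#' @param value the threshold energy.
#' @return a [ThresholdSpec-class] with `thetaPercent = NA`.
#' @export
thresholdFromEnergy <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  new("ThresholdSpec", thetaPercent = NA_real_, resolvedEnergy = value)
}

#' Cut an energy series into voice events and silences
#'
#' Maximal runs of consecutive samples with \eqn{\epsilon(t)} strictly above
#' the resolved threshold become tokens (voice events), each characterized
#' by the duple (\eqn{E_v} = sum of \eqn{\epsilon} over the run, \eqn{T_v} =
#' run length / rate); maximal runs at or below threshold become silence
#' gaps of duration \eqn{\tau}. Tokens and silences tile the series. Under
#' `boundaryPolicy = "drop"` the first and last run, which touch the series
#' edge and are possibly truncated, are removed from the statistics (their
#' counts are recorded in the `droppedTokens` / `droppedSilences` slots).
#'
#' @param e an [EnergySeries-class].
#' @param threshold a [ThresholdSpec-class] (from [resolveThreshold()] or
#'   [thresholdFromEnergy()]).
#' @param boundaryPolicy `"keep"` (default) or `"drop"`.
#' @return an [EventSequence-class]. Zero tokens is a legal outcome.
#' @export
extractEvents <- function(e, threshold, boundaryPolicy = c("keep", "drop")) {
  stopifnot(is(e, "EnergySeries"), is(threshold, "ThresholdSpec"))
  boundaryPolicy <- match.arg(boundaryPolicy)
  v <- e@values
  thr <- threshold@resolvedEnergy
  above <- v > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  csum <- c(0, cumsum(v))
  runEnergy <- csum[ends + 1L] - csum[starts]
  edge <- logical(length(r$lengths))
  if (length(edge)) edge[c(1L, length(edge))] <- TRUE
  isTok <- r$values
  keepRun <- if (boundaryPolicy == "drop") !edge else rep(TRUE, length(edge))

  tokIdx <- which(isTok & keepRun)
  silIdx <- which(!isTok & keepRun)
  tok <- data.frame(startIndex = starts[tokIdx] - 1L,
                    lengthSamples = r$lengths[tokIdx],
                    durationS = r$lengths[tokIdx] / e@rate,
                    energy = runEnergy[tokIdx])
  sil <- data.frame(startIndex = starts[silIdx] - 1L,
                    lengthSamples = r$lengths[silIdx],
                    durationS = r$lengths[silIdx] / e@rate)
  new("EventSequence", threshold = threshold, tokens = tok, silences = sil,
      seriesLength = length(v), rate = e@rate,
      boundaryPolicy = boundaryPolicy,
      droppedTokens = sum(isTok & edge & !keepRun),
      droppedSilences = sum(!isTok & edge & !keepRun))
}

#' Export an event sequence as a tidy data.frame
#'
#' One row per token and silence, with a `kind` column, in series order.
#'
#' @param events an [EventSequence-class].
#' @return a `data.frame` with columns `startIndex`, `lengthSamples`,
#'   `durationS`, `energy` (`NA` for silences), `kind`, `thetaPercent`.
#' @export
eventTable <- function(events) {
  stopifnot(is(events, "EventSequence"))
  tok <- events@tokens
  sil <- events@silences
  out <- rbind(
    if (nrow(tok)) cbind(tok, kind = "token") else NULL,
    if (nrow(sil)) cbind(sil, energy = NA_real_, kind = "silence")[,
      c("startIndex", "lengthSamples", "durationS", "energy", "kind")] else NULL)
  if (is.null(out))
    out <- data.frame(startIndex = integer(0), lengthSamples = integer(0),
                      durationS = numeric(0), energy = numeric(0),
                      kind = character(0))
  out <- out[order(out$startIndex), , drop = FALSE]
  out$thetaPercent <- events@threshold@thetaPercent
  rownames(out) <- NULL
  out
}
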