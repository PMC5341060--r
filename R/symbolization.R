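## Boundary tolerance for the half-open binning rule: an energy sitting at a
## bin edge up to one part in 1e9 of a bin below it is assigned to the upper
## bin, so that exact boundary values survive floating-point representation.
.BIN_EDGE_TOL <- 1e-9

#' Map tokens to types by binning their integrated energies
#'
#' Assigns each token the index of the energy bin its integrated energy
#' \eqn{E_v} falls into: `label = floor((E_v - E0) / b)` with half-open bins
#' \eqn{[E_0 + kb, E_0 + (k+1)b)}. Two tokens whose energies fall in the
#' same bin share a type even if their durations differ. The bin set is the
#' abstract vocabulary of the signal.
#'
#' With `binning = "log"` the same rule is applied to \eqn{\log E_v}
#' (geometric bins of ratio `1 + binWidth`), an alternative reading of the
#' symbolization step that is exposed for comparison but is not the default.
#'
#' @param events an [EventSequence-class] with at least one token.
#' @param binWidth bin size \eqn{b} in energy units; default 0.01.
#' @param origin bin origin \eqn{E_0}; default (`NULL`) is the minimum
#'   observed token energy. Supply an explicit value for cross-file
#'   comparability.
#' @param binning `"linear"` (default) or `"log"`.
#' @return a [TypeSequence-class] carrying labels, energies and durations.
#' @export
assignTypes <- function(events, binWidth = 0.01, origin = NULL,
                        binning = c("linear", "log")) {
  stopifnot(is(events, "EventSequence"))
  binning <- match.arg(binning)
  if (!is.numeric(binWidth) || length(binWidth) != 1 || binWidth <= 0)
    stop("binWidth must be a single positive number")
  E <- events@tokens$energy
  if (length(E) == 0)
    stop("cannot symbolize an event sequence with zero tokens")
  if (binning == "linear") {
    E0 <- if (is.null(origin)) min(E) else origin
    if (any(E < E0)) stop("origin must not exceed the smallest token energy")
    labels <- floor((E - E0) / binWidth + .BIN_EDGE_TOL)
  } else {
    E0 <- if (is.null(origin)) min(E) else origin
    if (E0 <= 0) stop("log binning requires a positive origin")
    labels <- floor(log(E / E0) / log1p(binWidth) + .BIN_EDGE_TOL)
  }
  new("TypeSequence", labels = labels, binWidth = binWidth, origin = E0,
      energies = E, durations = events@tokens$durationS)
}

#' Construct a TypeSequence from raw labels
#'
#' For symbol streams produced outside the binning step (e.g. synthetic
#' Zipf streams).
#'
#' @param labels nonnegative integer labels, one per token.
#' @param energies,durations optional aligned per-token metadata.
#' @param binWidth,origin bookkeeping for binned streams (`NA` otherwise).
#' @return a [TypeSequence-class].
#' @export
TypeSequence <- function(labels, energies = numeric(0),
                         durations = numeric(0), binWidth = NA_real_,
                         origin = NA_real_) {
  new("TypeSequence", labels = as.numeric(labels), binWidth = binWidth,
      origin = origin, energies = as.numeric(energies),
      durations = as.numeric(durations))
}

#' Vocabulary summary of a type sequence
#'
#' @param t a [TypeSequence-class].
#' @return a list with `V` (number of distinct types), `L` (number of
#'   tokens) and `typeTokenRatio` = V / L.
#' @export
vocabularyStats <- function(t) {
  stopifnot(is(t, "TypeSequence"))
  V <- length(unique(t@labels))
  L <- length(t@labels)
  list(V = V, L = L, typeTokenRatio = V / L)
}
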