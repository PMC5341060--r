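#' Shuffle surrogate of an energy series
#'
#' The null model of the method: a uniform random permutation of the
#' instantaneous-energy values. The marginal distribution is preserved
#' exactly (the surrogate is non-Gaussian white noise with the same
#' fat-tailed marginal) while all temporal correlation structure is
#' destroyed. An amplitude-domain shuffle is available for exploration by
#' passing an [AmplitudeSeries-class], but the energy-domain permutation is
#' the null model proper.
#'
#' @param e an [EnergySeries-class] (or an [AmplitudeSeries-class]).
#' @param seed explicit RNG seed (required for reproducibility).
#' @return an object of the same class with permuted values; rate and
#'   length preserved.
#' @export
shuffleSurrogate <- function(e, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(seed)
  if (is(e, "EnergySeries")) {
    EnergySeries(sample(e@values), e@rate,
                 sourceLabel = paste0(e@sourceLabel, " [surrogate]"))
  } else if (is(e, "AmplitudeSeries")) {
    AmplitudeSeries(sample(e@samples), e@rate,
                    sourceLabel = paste0(e@sourceLabel, " [surrogate]"),
                    normalized = e@normalized)
  } else stop("expected an EnergySeries or AmplitudeSeries")
}
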