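#' Construct a LawCurve
#'
#' Direct constructor, used by the law estimators and by synthetic
#' generators; `x` must be strictly increasing.
#'
#' @param lawId `"energy"`, `"zipf"`, `"heaps"` or `"brevity"`.
#' @param x,y curve coordinates.
#' @param thetaPercent threshold the curve belongs to (`NA` if none).
#' @param moments named list of rescaling quantities.
#' @return a [LawCurve-class].
#' @export
LawCurve <- function(lawId, x, y, thetaPercent = NA_real_, moments = list()) {
  new("LawCurve", lawId = lawId, x = as.numeric(x), y = as.numeric(y),
      thetaPercent = as.numeric(thetaPercent), moments = moments)
}

#' Energy-release distribution of the voice events
#'
#' Normalized log-binned density \eqn{P_\Theta(E)} of the integrated token
#' energies — the acoustic analogue of a Gutenberg-Richter law, expected to
#' be a power law \eqn{E^{-\phi}} saturated by an exponential cutoff. The
#' first two moments \eqn{\langle E\rangle, \langle E^2\rangle} are
#' recorded for the scaling collapse.
#'
#' @param events an [EventSequence-class] with at least two tokens.
#' @param ratio log-bin growth factor (default 1.3).
#' @param xmin optional lower limit \eqn{E_l}: the law's domain is
#'   \eqn{E > E_l}, and tokens below it are excluded from the density and
#'   the moments. Default `NULL` uses all tokens.
#' @return a [LawCurve-class] with `lawId = "energy"`; only occupied bins
#'   are kept.
#' @export
energyDistribution <- function(events, ratio = 1.3, xmin = NULL) {
  stopifnot(is(events, "EventSequence"))
  E <- events@tokens$energy
  if (!is.null(xmin)) E <- E[E >= xmin]
  if (length(E) < 2)
    stop("degenerate distribution: need at least two tokens")
  lb <- logBin(E, ratio)
  keep <- lb$counts > 0
  LawCurve("energy", lb$centers[keep], lb$density[keep],
           thetaPercent = events@threshold@thetaPercent,
           moments = list(meanE = mean(E), meanE2 = mean(E^2),
                          n = length(E)))
}

#' Zipf frequency spectrum of a type sequence
#'
#' For each occurrence count \eqn{n \ge 1}, the number \eqn{N_\Theta(n)} of
#' types occurring exactly \eqn{n} times. Satisfies \eqn{\sum_n N(n) = V}
#' and \eqn{\sum_n n N(n) = L} exactly. Zipf's law in this formulation is a
#' decay \eqn{N(n) \sim n^{-\zeta}}.
#'
#' @param t a [TypeSequence-class].
#' @param thetaPercent threshold to tag the curve with (optional).
#' @return a [LawCurve-class] with `lawId = "zipf"`; `moments` carries `V`,
#'   `L` and the per-type occurrence counts (`counts`), which are the
#'   samples to fit \eqn{\zeta} from.
#' @export
zipfSpectrum <- function(t, thetaPercent = NA_real_) {
  stopifnot(is(t, "TypeSequence"))
  counts <- as.numeric(table(t@labels))
  tab <- table(counts)
  n <- as.numeric(names(tab))
  o <- order(n)
  LawCurve("zipf", n[o], as.numeric(tab)[o], thetaPercent = thetaPercent,
           moments = list(V = length(counts), L = length(t@labels),
                          counts = counts))
}

#' Heaps vocabulary-growth curve
#'
#' Number of distinct types \eqn{V(k)} among the first \eqn{k} tokens, for
#' \eqn{k = 1 \dots L}. Sublinear growth \eqn{V \sim L^\alpha, \alpha < 1}
#' is Heaps' law; a constant rate of new types gives \eqn{\alpha = 1}.
#'
#' @param t a [TypeSequence-class].
#' @param thetaPercent threshold to tag the curve with (optional).
#' @return a [LawCurve-class] with `lawId = "heaps"`; non-decreasing,
#'   `y[1] = 1`, `y[L] = V`.
#' @export
heapsCurve <- function(t, thetaPercent = NA_real_) {
  stopifnot(is(t, "TypeSequence"))
  y <- cumsum(!duplicated(t@labels))
  LawCurve("heaps", seq_along(y), y, thetaPercent = thetaPercent,
           moments = list(V = y[length(y)], L = length(y)))
}

#' Brevity table: type frequency versus mean token duration
#'
#' For each type, the mean duration \eqn{t} of its tokens and its relative
#' frequency; the brevity law (law of abbreviation) requires the histogram
#' \eqn{M_\Theta(t)} to decrease with \eqn{t} — frequent types are short.
#' Types whose mean durations coincide are aggregated so the abscissa is
#' strictly increasing.
#'
#' @param t a [TypeSequence-class] whose `durations` slot is filled (as
#'   produced by [assignTypes()]).
#' @param thetaPercent threshold to tag the curve with (optional).
#' @return a [LawCurve-class] with `lawId = "brevity"`; frequencies sum
#'   to 1.
#' @export
brevityTable <- function(t, thetaPercent = NA_real_) {
  stopifnot(is(t, "TypeSequence"))
  if (!length(t@durations))
    stop("brevity table needs token durations aligned with labels")
  L <- length(t@labels)
  f <- factor(t@labels)
  meanDur <- as.numeric(tapply(t@durations, f, mean))
  freq <- as.numeric(table(f)) / L
  agg <- tapply(freq, meanDur, sum)  # merge duration ties
  x <- as.numeric(names(agg))
  o <- order(x)
  LawCurve("brevity", x[o], as.numeric(agg)[o], thetaPercent = thetaPercent,
           moments = list(meanDuration = mean(t@durations), L = L))
}

## ---- collapse --------------------------------------------------------------

.collapseOne <- function(curve) {
  m <- curve@moments
  switch(curve@lawId,
    energy = {
      if (is.null(m$meanE) || is.null(m$meanE2))
        stop("energy collapse needs moments meanE and meanE2")
      list(x = curve@x * m$meanE / m$meanE2,
           y = curve@y * m$meanE2^2 / m$meanE^3)
    },
    zipf = {
      if (is.null(m$V) || is.null(m$L))
        stop("zipf collapse needs V and L in moments")
      # abscissa in units of mean tokens per type (L/V); ordinate scaled by
      # 1/V so that the sum rule sum N(n) = V becomes sum = 1
      list(x = curve@x * m$V / m$L, y = curve@y / m$V)
    },
    heaps = {
      list(x = curve@x / max(curve@x), y = curve@y / max(curve@y))
    },
    brevity = {
      md <- if (!is.null(m$meanDuration)) m$meanDuration
            else sum(curve@x * curve@y) / sum(curve@y)
      list(x = curve@x / md, y = curve@y / sum(curve@y))
    })
}

.pairOverlap <- function(c1, c2, nGrid = 200) {
  ok1 <- c1$x > 0 & c1$y > 0
  ok2 <- c2$x > 0 & c2$y > 0
  if (sum(ok1) < 2 || sum(ok2) < 2) return(Inf)
  lo <- max(min(log10(c1$x[ok1])), min(log10(c2$x[ok2])))
  hi <- min(max(log10(c1$x[ok1])), max(log10(c2$x[ok2])))
  if (hi <= lo) return(Inf)
  g <- seq(lo, hi, length.out = nGrid)
  y1 <- approx(log10(c1$x[ok1]), log10(c1$y[ok1]), xout = g)$y
  y2 <- approx(log10(c2$x[ok2]), log10(c2$y[ok2]), xout = g)$y
  mean(abs(y1 - y2))
}

#' Collapse law curves measured at different thresholds
#'
#' Applies the threshold-collapse rescaling of each law and scores how well
#' the rescaled curves overlap. Threshold invariance of the collapsed
#' curves is the self-organized-criticality signature of the method.
#'
#' Rescalings: energy law uses the moment rescaling \eqn{E \to E\langle
#' E\rangle/\langle E^2\rangle}, \eqn{P \to P\langle E^2\rangle^2/\langle
#' E\rangle^3}; the Zipf spectrum rescales occurrence counts by the mean
#' tokens per type \eqn{L/V} and the ordinate by \eqn{1/V} (preserving the
#' sum rules); Heaps curves are rescaled by their endpoints
#' \eqn{(L_{max}, V_{max})}; brevity tables rescale duration by the mean
#' token duration and frequencies to unit sum.
#'
#' @param curves list of [LawCurve-class] objects sharing one `lawId`.
#' @return a list with `curves` (inputs with `xRescaled`/`yRescaled`
#'   filled) and `overlapScore`: the mean pairwise area between the
#'   rescaled curves' log-log interpolants on their common support, per
#'   unit log-abscissa. 0 means a perfect collapse; `Inf` flags pairs with
#'   no common support.
#' @export
collapseCurves <- function(curves) {
  if (is(curves, "LawCurve")) curves <- list(curves)
  stopifnot(length(curves) >= 1, all(vapply(curves, is, TRUE, "LawCurve")))
  ids <- unique(vapply(curves, function(cv) cv@lawId, ""))
  if (length(ids) != 1)
    stop("all curves must share one lawId; got: ", paste(ids, collapse = ", "))
  resc <- lapply(curves, .collapseOne)
  out <- mapply(function(cv, r) {
    cv@xRescaled <- r$x
    cv@yRescaled <- r$y
    cv
  }, curves, resc, SIMPLIFY = FALSE)
  score <- 0
  if (length(curves) > 1) {
    pairs <- combn(length(curves), 2)
    score <- mean(apply(pairs, 2, function(p)
      .pairOverlap(resc[[p[1]]], resc[[p[2]]])))
  }
  list(curves = out, overlapScore = score)
}

## ---- exponent fits on curves -----------------------------------------------

#' Fit the Heaps exponent from a vocabulary-growth curve
#'
#' Least squares on \eqn{\log V} versus \eqn{\log L} over a pre-saturation
#' window, evaluated on a log-spaced grid so all decades weigh equally.
#' Default window is \eqn{L \in [10, 0.1 L_{max}]}.
#'
#' @param curve a `"heaps"` [LawCurve-class].
#' @param window length-2 numeric, the L range to fit over; `NULL` for the
#'   default.
#' @param nGrid number of log-spaced evaluation points (default 50).
#' @return list with `alpha` (the slope) and `se` (its standard error).
#' @export
fitHeapsExponent <- function(curve, window = NULL, nGrid = 50) {
  stopifnot(is(curve, "LawCurve"), curve@lawId == "heaps")
  Lmax <- max(curve@x)
  if (is.null(window)) window <- c(10, 0.1 * Lmax)
  window[2] <- min(window[2], Lmax)
  if (window[2] <= window[1])
    stop("curve too short for the requested fitting window")
  g <- unique(round(exp(seq(log(window[1]), log(window[2]),
                            length.out = nGrid))))
  yv <- curve@y[match(g, curve@x)]
  ok <- !is.na(yv) & yv > 0
  fit <- stats::lm(log(yv[ok]) ~ log(g[ok]))
  # degenerate streams (all-new or all-repeated types) fit perfectly
  list(alpha = unname(coef(fit)[2]),
       se = suppressWarnings(summary(fit)$coefficients[2, 2]))
}

#' Fit the brevity decay exponent from a brevity table
#'
#' Least squares of \eqn{\log M} on \eqn{\log t} over the initial decay
#' region (durations up to the median abscissa by default), where the
#' brevity law shows its power-law decay \eqn{M(t) \sim t^{-\beta}}.
#'
#' @param curve a `"brevity"` [LawCurve-class].
#' @param tmax upper duration limit of the fit region; `NULL` uses the
#'   median abscissa.
#' @return list with `beta` (positive decay exponent) and `se`.
#' @export
fitBrevityExponent <- function(curve, tmax = NULL) {
  stopifnot(is(curve, "LawCurve"), curve@lawId == "brevity")
  if (is.null(tmax)) tmax <- stats::median(curve@x)
  ok <- curve@x <= tmax & curve@y > 0 & curve@x > 0
  if (sum(ok) < 3) stop("too few points in the brevity fit region")
  fit <- stats::lm(log(curve@y[ok]) ~ log(curve@x[ok]))
  # an exactly power-law table fits perfectly; summary() warns then
  list(beta = -unname(coef(fit)[2]),
       se = suppressWarnings(summary(fit)$coefficients[2, 2]))
}

## ---- exponent relations ----------------------------------------------------

#' Algebraic relations between the scaling exponents
#'
#' Fills missing exponents from the stated identities, without touching any
#' value that was supplied: \eqn{\zeta = 1 + 1/z} (Zipf spectrum vs rank
#' form), \eqn{\zeta = 1 + \alpha} (Zipf-Heaps link), \eqn{\alpha' =
#' \alpha/(1+\alpha)} (collapsed Heaps exponent), and the prediction
#' \eqn{z \approx \phi} linking the energy-release exponent to the rank
#' exponent, reported as `zetaPred` \eqn{= 1 + 1/\phi}.
#'
#' @param phi energy-release exponent.
#' @param zeta Zipf frequency-spectrum exponent.
#' @param z Zipf rank exponent (> 0).
#' @param alpha Heaps growth exponent.
#' @param alphaPrime collapsed Heaps exponent (< 1).
#' @param beta brevity decay exponent (carried through, no relations).
#' @return named list of exponents (`NA` where underivable) with a
#'   `provenance` attribute marking each as `"given"` or `"derived"`.
#' @export
exponentRelations <- function(phi = NA, zeta = NA, z = NA, alpha = NA,
                              alphaPrime = NA, beta = NA) {
  if (!is.na(z) && z <= 0) stop("z must be > 0")
  if (!is.na(alphaPrime) && alphaPrime >= 1)
    stop("alphaPrime must be < 1")
  if (!is.na(alphaPrime) && alphaPrime < 0)
    stop("alphaPrime must be >= 0")
  v <- c(phi = phi, zeta = zeta, z = z, alpha = alpha,
         alphaPrime = alphaPrime, beta = beta, zetaPred = NA)
  prov <- ifelse(is.na(v), NA_character_, "given")
  fill <- function(name, value) {
    if (is.na(v[[name]]) && !is.na(value)) {
      v[[name]] <<- value
      prov[[name]] <<- "derived"
    }
  }
  for (pass in 1:3) {
    fill("alpha", if (!is.na(v[["alphaPrime"]]))
      v[["alphaPrime"]] / (1 - v[["alphaPrime"]]) else NA)
    fill("zeta", if (!is.na(v[["z"]])) 1 + 1 / v[["z"]] else NA)
    fill("zeta", if (!is.na(v[["alpha"]])) 1 + v[["alpha"]] else NA)
    fill("z", if (!is.na(v[["zeta"]]) && v[["zeta"]] > 1)
      1 / (v[["zeta"]] - 1) else NA)
    fill("alpha", if (!is.na(v[["zeta"]])) v[["zeta"]] - 1 else NA)
    fill("alphaPrime", if (!is.na(v[["alpha"]]))
      v[["alpha"]] / (1 + v[["alpha"]]) else NA)
    fill("zetaPred", if (!is.na(v[["phi"]])) 1 + 1 / v[["phi"]] else NA)
  }
  out <- as.list(v)
  attr(out, "provenance") <- prov
  out
}
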