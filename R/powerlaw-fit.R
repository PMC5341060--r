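## ---- special functions -----------------------------------------------------

## Hurwitz zeta(s, q) = sum_{k>=0} (q + k)^(-s), s > 1, q > 0, by direct
## summation plus an Euler-Maclaurin tail. Accurate to ~1e-13 for the
## exponent ranges met here.
.hurwitzZeta <- function(s, q) {
  stopifnot(s > 1, q > 0)
  N <- 25
  k <- 0:(N - 1)
  head <- sum((q + k)^(-s))
  a <- q + N
  tail <- a^(1 - s) / (s - 1) + a^(-s) / 2 +
    s * a^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * a^(-s - 3) / 720 +
    s * (s + 1) * (s + 2) * (s + 3) * (s + 4) * a^(-s - 5) / 30240
  head + tail
}

## ---- internal samplers -----------------------------------------------------

## Continuous Pareto: density (a-1)/xmin * (x/xmin)^(-a), x >= xmin,
## optionally truncated at xmax. Inverse-CDF; u = 0 maps to xmin.
.rpareto <- function(n, exponent, xmin, xmax = Inf) {
  u <- runif(n)
  if (is.finite(xmax)) {
    w <- 1 - (xmax / xmin)^(1 - exponent)
    xmin * (1 - u * w)^(-1 / (exponent - 1))
  } else {
    xmin * (1 - u)^(-1 / (exponent - 1))
  }
}

## Discrete power law ("zeta distribution" generalized to xmin):
## P(X = k) = k^(-a) / zeta(a, xmin), k = xmin, xmin+1, ...
## Exact inversion over a finite table, continuous-tail approximation
## beyond it (relative pmf error < 1/K there).
.rzeta <- function(n, exponent, xmin, tableMax = 100000) {
  Z <- .hurwitzZeta(exponent, xmin)
  k <- xmin:tableMax
  pmf <- k^(-exponent) / Z
  cdf <- cumsum(pmf)
  pTable <- cdf[length(cdf)]
  u <- runif(n)
  out <- numeric(n)
  inTab <- u <= pTable
  out[inTab] <- k[findInterval(u[inTab], cdf, left.open = TRUE) + 1L]
  nt <- sum(!inTab)
  if (nt) {
    # Pareto tail conditioned on X > tableMax; floor keeps it integer.
    # At k > 1e5 the continuous approximation to the zeta pmf is exact to
    # better than 1e-5 relative.
    v <- runif(nt)
    out[!inTab] <- floor((tableMax + 0.5) * (1 - v)^(-1 / (exponent - 1)) + 0.5)
  }
  out
}

## ---- KS distances ----------------------------------------------------------

.paretoCdf <- function(x, exponent, xmin, xmax = Inf) {
  Fx <- 1 - (x / xmin)^(1 - exponent)
  if (is.finite(xmax)) Fx <- Fx / (1 - (xmax / xmin)^(1 - exponent))
  Fx
}

.ksContinuous <- function(xsorted, exponent, xmin, xmax = Inf) {
  n <- length(xsorted)
  Fx <- .paretoCdf(xsorted, exponent, xmin, xmax)
  i <- seq_len(n)
  max(pmax(i / n - Fx, Fx - (i - 1) / n))
}

.ksDiscrete <- function(x, exponent, xmin) {
  n <- length(x)
  ux <- sort(unique(x))
  ecdf <- cumsum(tabulate(factor(x, levels = ux))) / n
  Z <- .hurwitzZeta(exponent, xmin)
  Fx <- 1 - vapply(ux + 1, function(q) .hurwitzZeta(exponent, q), 0) / Z
  max(abs(ecdf - Fx))
}

## ---- MLE -------------------------------------------------------------------

.mleContinuous <- function(x, xmin, xmax = Inf) {
  n <- length(x)
  if (!is.finite(xmax))
    return(1 + n / sum(log(x / xmin)))
  S <- sum(log(x))
  nll <- function(a) {
    -(n * log((a - 1) / (xmin^(1 - a) - xmax^(1 - a))) - a * S)
  }
  optimize(nll, c(1 + 1e-8, 50))$minimum
}

.mleDiscrete <- function(x, xmin) {
  n <- length(x)
  S <- sum(log(x))
  nll <- function(a) n * log(.hurwitzZeta(a, xmin)) + a * S
  optimize(nll, c(1 + 1e-6, 50))$minimum
}

## ---- public fitting interface ----------------------------------------------

#' Fit a power law by maximum likelihood
#'
#' Continuous data use the closed-form MLE \eqn{\hat\alpha = 1 + n / \sum
#' \ln(x_i/x_{min})} over the tail \eqn{x \ge x_{min}}; discrete (integer)
#' data maximize the zeta-function likelihood numerically. The lower cutoff
#' can be fixed or selected by scanning candidate values for the minimal
#' Kolmogorov-Smirnov distance between tail data and fitted model (the
#' Clauset-Shalizi-Newman recipe). An optional `xmax` restricts the fit
#' window below an exponential cutoff. The confidence half-width comes from
#' a nonparametric bootstrap of the tail.
#'
#' @param x positive numeric samples (positive integers when
#'   `discrete = TRUE`).
#' @param discrete use the discrete (zeta) likelihood.
#' @param xmin lower cutoff; `NULL` (default) selects it by KS scan.
#' @param xmax optional upper fit limit (default `Inf`). Samples above it
#'   are excluded from the tail.
#' @param nCi bootstrap replicates for the exponent confidence half-width
#'   (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @param minTail minimum tail size required (default 10).
#' @return a [PowerLawFit-class]. Run [gofPValue()] for the bootstrap
#'   p-value.
#' @export
fitPowerLaw <- function(x, discrete = FALSE, xmin = NULL, xmax = Inf,
                        nCi = 200, seed = 1, minTail = 10) {
  if (any(x <= 0) || !all(is.finite(x)))
    stop("samples must be positive and finite")
  if (discrete && any(x != floor(x)))
    stop("discrete fitting requires integer samples")
  scan <- is.null(xmin)
  if (scan) {
    cand <- sort(unique(x))
    cand <- cand[seq_len(max(1, length(cand) - minTail + 1))]
    if (length(cand) > 150)
      cand <- unique(quantile(cand, probs = seq(0, 1, length.out = 150),
                              type = 1))
    best <- NULL
    for (xm in cand) {
      tail <- x[x >= xm & x <= xmax]
      if (length(tail) < minTail) next
      a <- if (discrete) .mleDiscrete(tail, xm) else .mleContinuous(tail, xm, xmax)
      D <- if (discrete) .ksDiscrete(tail, a, xm)
           else .ksContinuous(sort(tail), a, xm, xmax)
      if (is.null(best) || D < best$D) best <- list(xmin = xm, a = a, D = D)
    }
    if (is.null(best)) stop("insufficient data: no candidate xmin leaves ",
                            minTail, " tail samples")
    xmin <- best$xmin; ahat <- best$a; D <- best$D
  } else {
    tail <- x[x >= xmin & x <= xmax]
    if (length(tail) < minTail)
      stop("insufficient data: fewer than ", minTail, " samples above xmin")
    ahat <- if (discrete) .mleDiscrete(tail, xmin)
            else .mleContinuous(tail, xmin, xmax)
    D <- if (discrete) .ksDiscrete(tail, ahat, xmin)
         else .ksContinuous(sort(tail), ahat, xmin, xmax)
  }
  tail <- x[x >= xmin & x <= xmax]
  ci <- NA_real_
  if (nCi > 0) {
    set.seed(seed)
    boots <- vapply(seq_len(nCi), function(i) {
      b <- sample(tail, replace = TRUE)
      if (discrete) .mleDiscrete(b, xmin) else .mleContinuous(b, xmin, xmax)
    }, 0)
    ci <- 1.96 * sd(boots)
  }
  new("PowerLawFit", exponent = ahat, xmin = as.numeric(xmin), xmax = xmax,
      ksStat = D, ciHalfwidth = ci, nTail = length(tail),
      discrete = discrete, seed = as.numeric(seed))
}

#' Bootstrap goodness-of-fit p-value for a power-law fit
#'
#' Parametric KS bootstrap: for each replicate, `nTail` points are sampled
#' from the fitted model, the exponent is refitted (at the fit's `xmin`),
#' and the replicate's KS distance to its own best fit is recorded. The
#' p-value is the fraction of replicate KS distances greater than or equal
#' to the empirical KS distance, so small p rejects the power-law
#' hypothesis (the standard Clauset convention). Default is 2500
#' replicates.
#'
#' @param fit a [PowerLawFit-class].
#' @param x the samples the fit was computed from.
#' @param nBoot bootstrap replicates (default 2500; < 100 warns).
#' @param seed RNG seed.
#' @return the fit with `pValue`, `nBoot` and `seed` slots filled.
#' @export
gofPValue <- function(fit, x, nBoot = 2500, seed = 1) {
  stopifnot(is(fit, "PowerLawFit"))
  if (nBoot < 100)
    warning("fewer than 100 bootstrap replicates gives a coarse p-value")
  n <- fit@nTail
  if (n < 2) stop("degenerate fit: tail too small for a bootstrap")
  set.seed(seed)
  Dstar <- numeric(nBoot)
  for (i in seq_len(nBoot)) {
    if (fit@discrete) {
      b <- .rzeta(n, fit@exponent, fit@xmin)
      a <- .mleDiscrete(b, fit@xmin)
      Dstar[i] <- .ksDiscrete(b, a, fit@xmin)
    } else {
      b <- .rpareto(n, fit@exponent, fit@xmin, fit@xmax)
      a <- .mleContinuous(b, fit@xmin, fit@xmax)
      Dstar[i] <- .ksContinuous(sort(b), a, fit@xmin, fit@xmax)
    }
  }
  fit@pValue <- mean(Dstar >= fit@ksStat)
  fit@nBoot <- as.integer(nBoot)
  fit@seed <- as.numeric(seed)
  fit
}

## ---- logarithmic binning ---------------------------------------------------

#' Logarithmically binned density estimate
#'
#' Histogram with geometrically spaced bin edges (constant edge ratio),
#' the standard estimator for heavy-tailed densities. Counts are conserved
#' and the density integrates to one.
#'
#' @param x positive samples.
#' @param ratio bin-edge growth factor (> 1; default 1.3).
#' @return a list with `edges`, `centers` (geometric bin centers),
#'   `counts` and `density` (count / (n * width)).
#' @export
logBin <- function(x, ratio = 1.3) {
  if (any(x <= 0)) stop("logarithmic binning requires positive samples")
  if (ratio <= 1) stop("ratio must exceed 1")
  lo <- min(x); hi <- max(x)
  nb <- if (hi == lo) 1L else ceiling(log(hi / lo) / log(ratio) - 1e-9)
  edges <- lo * ratio^(0:nb)
  # guard against the top sample falling on/over the last edge
  edges[length(edges)] <- max(edges[length(edges)], hi * (1 + 1e-12))
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx > nb] <- nb
  counts <- tabulate(idx, nbins = nb)
  widths <- diff(edges)
  list(edges = edges, centers = sqrt(edges[-1] * edges[-length(edges)]),
       counts = counts, density = counts / (length(x) * widths))
}
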