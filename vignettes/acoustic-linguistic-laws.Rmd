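---
title: "Measuring linguistic laws in acoustic signals by energy thresholding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring linguistic laws in acoustic signals by energy thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voicelaws)
```

## The method

Classical linguistic laws — Zipf's law, Heaps' law, the brevity law — are
usually measured on written corpora, which presupposes a segmentation of
the signal into words. `voicelaws` implements a segmentation-free
alternative that operates directly on the physics of an acoustic signal:

1. **Energy.** A mono waveform $A(t)$ is squared into the instantaneous
   energy $\varepsilon(t) = |A(t)|^2$ (constants dropped).
2. **Thresholding.** A threshold $\Theta$, declared as the percentage of
   samples kept at or above the resolved energy level ($\Theta = 80\%$
   leaves 20% of samples strictly below), cuts the series into maximal
   runs: runs with $\varepsilon(t)$ strictly above the threshold are
   *tokens* (voice events), runs at or below are silences of duration
   $\tau$. Each token carries the duple $(E_v, T_v)$: its integrated
   energy and its duration.
3. **Symbolization.** Token energies are linearly binned with bin size
   $b = 0.01$; tokens sharing a bin share a *type*, the abstract "word".
   The set of occupied bins is the vocabulary $V$; the token count is $L$.
4. **Laws.** Four statistics are computed per threshold: the energy-release
   distribution $P_\Theta(E)$ (a Gutenberg–Richter analogue, expected to be
   $E^{-\phi}$ with an exponential cutoff at scale $E_\xi$, valid above a
   lower limit $E_l$); the Zipf frequency spectrum $N_\Theta(n)$, the
   number of types occurring exactly $n$ times, expected to decay as
   $n^{-\zeta}$; the Heaps vocabulary-growth curve $V(L)\sim L^\alpha$;
   and the brevity table $M_\Theta(t)$ of type frequency against mean
   token duration, expected to decrease (frequent types are short) with an
   initial power-law decay $t^{-\beta}$.
5. **Collapse.** If the signal is scale-invariant under thresholding (the
   self-organized-criticality signature), curves at different $\Theta$
   collapse onto master curves: the energy law under the moment rescaling
   $E \to E\langle E\rangle/\langle E^2\rangle$,
   $P \to P\langle E^2\rangle^2/\langle E\rangle^3$; the Zipf spectrum
   under $n \to nV/L$, $N \to N/V$; Heaps curves by their endpoints; the
   brevity table by the mean token duration and unit frequency sum. A
   numeric overlap score (mean pairwise area between the rescaled log–log
   interpolants on their common support, per unit log-abscissa) replaces
   the visual judgement: 0 is a perfect collapse.
6. **Null model.** A uniform random permutation of $\varepsilon(t)$
   preserves the marginal energy distribution and destroys all temporal
   structure. A structured signal should collapse; its surrogate should
   not.

Exponent fits use maximum likelihood: the closed form
$\hat\alpha = 1 + n/\sum\ln(x_i/x_{min})$ for continuous tails, the
numerically maximized zeta-function likelihood for discrete data, with the
lower cutoff selected by a Kolmogorov–Smirnov scan and goodness of fit by
parametric KS bootstrap (p = fraction of model-simulated replicates whose
KS distance to their own best fit is at least the empirical one; 2500
replicates by default). The exponents are linked algebraically:
$\zeta = 1 + 1/z$ (spectrum vs rank form), $z \approx \phi$,
$\zeta = 1 + \alpha$, and the collapsed Heaps exponent
$\alpha' = \alpha/(1+\alpha)$; `exponentRelations()` derives any missing
member and the pipeline reports the identities as diagnostics, not
assertions.

## Parameters that matter

* `thetaPercent` — the only free parameter of the method. The default
  grid is {30, 40, 50, 60, 70, 80, 90} percent. Note the convention:
  higher $\Theta$ means a *lower* energy threshold (more samples kept).
* `binWidth` (`b`, energy units, default 0.01) — the type resolution.
  Tokens are dimensionless squared-amplitude sums with full-scale
  normalized audio, which is what makes 0.01 meaningful across files.
  Linear binning defines type identity; logarithmic binning is used only
  to estimate heavy-tailed densities. (`typeBinning = "log"` exposes the
  alternative reading in which types themselves are log-binned.)
* `origin` (`E0`) — the first bin edge; defaults to the minimum observed
  token energy, with an explicit override for cross-file comparability.
* Tie and boundary rules: samples exactly equal to the threshold are
  silence (the voice definition is strictly `>`); the resolved threshold
  is the order statistic of rank `floor(q N) + 1`, `q = (100 − Θ)/100`,
  so the fraction strictly below never exceeds `q`; energies exactly on a
  bin edge go to the upper bin (tolerance one part in 1e9 of a bin).
  Edge-touching runs are kept by default (`boundaryPolicy = "keep"`
  preserves the conservation identities; `"drop"` is available for short
  series where truncation bias matters).
* Fit windows: the Heaps exponent is fitted by least squares on
  $\log V$ vs $\log L$ over a log-spaced grid in $[10, 0.1\,L_{max}]$ —
  a pre-saturation window; the brevity exponent over the initial decay
  region (abscissae up to the median). Both windows are explicit
  arguments.

## The synthetic generator

No audio corpus ships with the package; every claim is tested against
seedable generators with known ground truth.

`synthVoiceSignal()` emulates the statistical structure the method
assumes: alternating silence gaps (power-law durations, exponent 2 — the
literature reports power-law-distributed silences but no specific value,
so the canonical inverse-square law is used) and voice events whose
integrated energies follow a power law of exponent `phiTrue = 1.15` with
an exponential cutoff, spread over durations $T \propto E^{1/2}$ (longer
events carry more energy, the brevity-compatible geometry) with a
raised-cosine within-event profile riding on a small pedestal. The
pedestal keeps every event sample above a *design threshold* placed
between the silence floor and the pedestal, at which segmentation
recovers the generated events exactly — the generator returns that
threshold along with the ground-truth event list.

Scale choices, made once: event energies start at $x_{min} = 1$ with
cutoff $10^5$ (five decades of scaling range, as in wide-band speech);
with $b = 0.01$ the low-energy bins then agglutinate tens of tokens each,
so the vocabulary is nontrivial (about 0.6 types per token at
$L = 2\times10^4$) and the binned occupancy inherits the Zipf structure
with the predicted $\zeta \approx 1 + 1/\phi$. Gaps start at 16 samples
(1 ms at 16 kHz) and events average a few ms, giving a voice-activity
fraction around 55%, typical of continuous broadcast speech.

What the generator does *not* emulate: within-event self-similar
fluctuations (real voice is believed to be near a critical state; the
generated bumps are smooth), background-noise correlations (silence
samples are i.i.d. uniform below the floor), and any dependence between
consecutive events. Consequently the generated signal is threshold-
*invariant* only for thresholds that resolve below the event pedestal —
for thresholds inside the silence band the segmentation recovers the
designed events plus a dust of sub-$E_l$ noise fragments, and the energy
law is evaluated on its domain $E \ge E_l$ (the `xmin` argument of
`energyDistribution()`). Passing tests therefore demonstrate that the
*machinery* (segmentation, symbolization, law estimation, collapse
scoring, null-model contrast) behaves correctly on signals with known
structure, not that any particular real recording is critical.

The symbolic generators are independent of the signal path:
`zipfStream()` draws i.i.d. tokens with rank probabilities
$p(r) \propto r^{-z}$ (unbounded vocabularies via a rank distribution
truncated at rank $10^8$ with mass renormalized, realized as the floor of
a truncated continuous power law), for which $V(L) \sim L^{1/z}$ when
$z > 1$; `brevitySynth()` builds a frequency–duration table with an exact
decay exponent; `powerlawSamples()` draws continuous (inverse-CDF, with
optional exponential cutoff by rejection) or discrete (exact inversion of
the zeta law with a continuous-tail approximation beyond rank $10^5$)
power-law samples.

## Numerical choices

* The Hurwitz zeta normalization of the discrete likelihood is computed
  by direct summation plus an Euler–Maclaurin tail (25 head terms, three
  correction terms; accurate to ~1e-13 in the relevant exponent range).
* The KS scan over candidate lower cutoffs caps the candidate set at 150
  quantiles of the observed values; each candidate must leave at least 10
  tail samples.
* The exponential cutoff $E_\xi$ visible in energy distributions is
  handled by restricting the fit window (`xmax`), not by a truncated
  likelihood; with `xmax` finite the continuous MLE is maximized
  numerically for the truncated density.
* The collapse overlap score interpolates $\log_{10} y$ against
  $\log_{10} x$ on 200 grid points over the pairwise common support;
  pairs with no common support score `Inf` (a diagnosed non-collapse).
  The score is invariant under curve order and zero for identical curves.
* Bootstrap p-values follow the convention that *larger* replicate KS
  distances support the power-law hypothesis; at the default 2500
  replicates the p-value granularity is 4e-4.
* Degenerate inputs: constant energy series cannot resolve a percentile
  threshold (every value is tied) and are reported as such; a threshold
  yielding fewer than `minTokens` tokens is reported empty and the
  multi-threshold pipeline continues; a constant-zero input yields a
  clean all-empty report.

## Design decisions that were genuinely open

* **Normalization.** Audio integer samples are divided by the full scale
  of their width (16-bit: 32768) before squaring; nothing in the method
  fixes physical units, and full-scale normalization is what makes the
  default bin width portable across recordings. An off-switch
  (`normalize = FALSE`) is provided.
* **Linear vs logarithmic type binning.** Type identity uses linear
  binning of integrated energies; the log-binned alternative is exposed
  as an option but is not the default (log binning is reserved for
  density estimation).
* **Zipf collapse normalization.** The rescaling is implemented as
  $n \to nV/L$, $N \to N/V$, the reading that preserves the sum rules
  ($\sum N/V = 1$, $\sum (nV/L)(N/V) = 1$); the tested contract is the
  overlap score, not a particular constant.
* **Heaps and brevity collapses** use endpoint and mean-duration
  rescaling respectively — the simplest normalization-preserving
  reconstructions.
* **Robustness to `b`** is asserted against fixed bands (Zipf exponent
  shifts under halving/doubling `b` stay below 0.15, Heaps below 0.05 on
  the reference synthetic signal): coarsening the vocabulary shifts
  exponents systematically, by more than the purely statistical fit
  error, so a band — not the fit's confidence half-width — is the honest
  tolerance.

## Problem sizes used in the shipped tests

The test-suite and the acceptance script run entirely from generators:
$10^5$ continuous and $5\times10^4$ discrete power-law samples for
exponent recovery, a $10^6$-token Zipf stream for Heaps growth (fitted
over $L \in [100, 10^5]$), a $10^4$-type brevity table, a
$2\times10^4$-event synthetic signal (about $7\times10^6$ samples) for
the pipeline and null-model contrast, $5\times10^4$ events for the
headline energy-exponent recovery, and 200 runs of 250 bootstrap
replicates for the p-value calibration. These sizes put Monte-Carlo
error comfortably inside the asserted tolerances.

## Limitations

* The package measures statistical structure; it does not perform voice
  activity detection in the engineering sense (no hysteresis, no minimum
  gap merging, no noise adaptation), and types have no claimed relation
  to phonemes or words.
* Compressed codecs are out of scope; inputs are PCM WAV, raw integer
  streams, or precomputed energy columns.
* The exponent of real recordings depends on recording conditions through
  the threshold; the collapse machinery quantifies, but does not remove,
  that dependence for signals that are not scale-invariant.
* Likelihood-ratio comparisons against alternative heavy-tailed families
  (lognormal, stretched exponential) are not implemented; the KS
  bootstrap answers "is the power law rejected", not "is it the best
  model".
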