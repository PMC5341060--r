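# voicelaws

Linguistic laws in acoustic signals, measured without segmentation into
words.

## The problem

Zipf's law, Heaps' law and the brevity law are cornerstones of
quantitative linguistics, but they are usually measured on written
corpora — which presupposes a language-dependent segmentation of the
signal. `voicelaws` implements a segmentation-free method that works on
any acoustic signal: it thresholds the instantaneous energy
ε(t) = |A(t)|², so that maximal runs above the threshold become *tokens*
(voice events, each a duple (E_v, T_v) of integrated energy and
duration) and runs below become silences; linear binning of token
energies (bin size b = 0.01) maps tokens to *types*, the abstract words.
On the resulting symbol stream the package measures, per threshold Θ:

* the energy-release distribution P_Θ(E) ~ E^(−φ) with exponential
  cutoff (a Gutenberg–Richter analogue);
* Zipf's frequency spectrum N_Θ(n) ~ n^(−ζ), the number of types
  occurring exactly n times;
* Heaps' vocabulary growth V ~ L^α;
* the brevity law M_Θ(t): type frequency decreasing with mean token
  duration, with initial decay t^(−β);

plus the threshold-collapse rescalings (e.g. E → E⟨E⟩/⟨E²⟩,
P → P⟨E²⟩²/⟨E⟩³) whose success signals scale invariance, the algebraic
exponent relations (ζ = 1 + 1/z, z ≈ φ, ζ = 1 + α, α′ = α/(1+α)),
maximum-likelihood power-law fits with KS-bootstrap goodness of fit, and
shuffle surrogates as null models. Seedable synthetic generators with
known ground-truth exponents make every stage testable without any audio
corpus. The intended users are researchers in bioacoustics, quantitative
linguistics and complex systems who want these statistics on signals for
which no transcript exists.

## Worked example

```r
library(voicelaws)

# a synthetic voice-like signal with known structure: 5000 events whose
# energies follow a power law of exponent 1.15 with cutoff
s <- synthVoiceSignal(5000, seed = 1)

# segment at the generator's design threshold and symbolize
ev <- extractEvents(s$energy, thresholdFromEnergy(s$designThreshold))
ts <- assignTypes(ev, binWidth = 0.01)
vocabularyStats(ts)
#> $V
#> [1] 3649
#> $L
#> [1] 5000
#> $typeTokenRatio
#> [1] 0.7298

# recover the energy exponent by MLE below the cutoff
fitPowerLaw(tokens(ev)$energy, xmin = 1, xmax = 1e4, nCi = 0)
#> PowerLawFit (continuous): exponent = 1.1659, xmin = 1, n_tail = 4633, KS = 0.008449

# or run the whole multi-threshold pipeline on a WAV file
# e <- energySeries(loadAudio("speech.wav"))
b <- runPipeline(s$energy, thetaGrid = c(70, 80, 90), seed = 1)
print(b$exponents[, c("theta", "phi", "zeta", "alpha", "beta")], digits = 3)
#>   theta  phi zeta alpha  beta
#> 1    70 1.26 2.94 0.801 0.539
#> 2    80 1.26 2.94 0.787 0.563
#> 3    90 1.27 2.95 0.800 0.626
```

The fitted exponent 1.166 recovers the generating value 1.15 within a
few standard errors (the per-threshold `phi` column runs the automatic
KS scan for the lower cutoff instead of using the generator's known
values, and the percentile thresholds admit sub-cutoff noise fragments,
so its estimates sit higher). `b$collapse$energy$overlapScore`
quantifies how well the per-threshold energy distributions collapse
after moment rescaling (0 = perfect); restricted to the law's domain
`E >= 1` the synthetic signal scores near zero while the same pipeline
with `surrogate = TRUE` scores two orders of magnitude worse — the
null-model contrast.

A thin command-line front end is installed with the package
(`system.file("cli", "voicelaws", package = "voicelaws")`) with
subcommands `analyze`, `nullmodel`, `simulate`, `fit` and `collapse`.

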