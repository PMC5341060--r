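Package: voicelaws
Title: Linguistic Laws in Acoustic Signals via Energy Thresholding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments arbitrary acoustic signals into voice events and
    silences by thresholding the instantaneous energy, symbolizes events
    into energy-bin types, and measures the statistical laws of the
    resulting token stream: the power-law distribution of event energies
    (a Gutenberg-Richter analogue), Zipf's law of type frequencies,
    Heaps' law of vocabulary growth, and the brevity law linking type
    frequency to mean event duration. Includes threshold-collapse
    rescalings for testing scale invariance, maximum-likelihood power-law
    fitting with Kolmogorov-Smirnov bootstrap goodness of fit, shuffle
    surrogates as null models, and seedable synthetic generators with
    known ground-truth exponents.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'signal-io.R'
    'segmentation.R'
    'symbolization.R'
    'powerlaw-fit.R'
    'laws.R'
    'surrogates.R'
    'synthetic.R'
    'pipeline.R'
    'report-io.R'
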