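# In-code fixture builders: tiny WAV/raw files and event sequences.

# Minimal PCM WAV writer (little-endian), enough to exercise the reader.
writeWavFixture <- function(path, samples, rate = 16000, bits = 16,
                            channels = 1, float = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  bytesPerSample <- bits / 8
  dataSize <- length(samples) * bytesPerSample
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (float) 3 else 1), con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * channels * bytesPerSample), con, size = 4,
           endian = "little")
  writeBin(as.integer(channels * bytesPerSample), con, size = 2,
           endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (float) {
    writeBin(as.double(samples), con, size = bytesPerSample,
             endian = "little")
  } else {
    writeBin(as.integer(samples), con, size = bytesPerSample,
             endian = "little")
  }
  invisible(path)
}

# An EventSequence carrying given token energies/durations, for
# symbolization tests that do not need a real signal.
eventSeqFromTokens <- function(energies, durationsS = NULL, rate = 1) {
  n <- length(energies)
  if (is.null(durationsS)) durationsS <- rep(1, n)
  new("EventSequence",
      threshold = thresholdFromEnergy(0),
      tokens = data.frame(startIndex = seq_len(n) - 1L,
                          lengthSamples = pmax(1L, as.integer(durationsS * rate)),
                          durationS = durationsS, energy = energies),
      silences = data.frame(startIndex = integer(0),
                            lengthSamples = integer(0),
                            durationS = numeric(0)),
      seriesLength = n, rate = rate, boundaryPolicy = "keep",
      droppedTokens = 0L, droppedSilences = 0L)
}

# Brute-force per-sample run scan: the segmentation oracle.
naiveRunScan <- function(values, thr) {
  tok <- list(); sil <- list()
  i <- 1; n <- length(values)
  while (i <= n) {
    above <- values[i] > thr
    j <- i
    while (j < n && (values[j + 1] > thr) == above) j <- j + 1
    seg <- list(start = i - 1L, len = j - i + 1L,
                energy = sum(values[i:j]))
    if (above) tok[[length(tok) + 1]] <- seg else sil[[length(sil) + 1]] <- seg
    i <- j + 1
  }
  list(tokens = tok, silences = sil)
}
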