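#' Construct an AmplitudeSeries
#'
#' @param samples numeric amplitude vector.
#' @param rate sampling rate in Hz.
#' @param sourceLabel free-text provenance.
#' @param normalized whether samples are full-scale normalized to `[-1, 1]`.
#' @return an [AmplitudeSeries-class] object.
#' @export
AmplitudeSeries <- function(samples, rate, sourceLabel = "",
                            normalized = TRUE) {
  new("AmplitudeSeries", samples = as.numeric(samples),
      rate = as.numeric(rate), sourceLabel = sourceLabel,
      normalized = normalized)
}

#' Construct an EnergySeries
#'
#' @param values nonnegative instantaneous-energy vector.
#' @param rate sampling rate in Hz.
#' @param sourceLabel free-text provenance.
#' @return an [EnergySeries-class] object.
#' @export
EnergySeries <- function(values, rate, sourceLabel = "") {
  new("EnergySeries", values = as.numeric(values), rate = as.numeric(rate),
      sourceLabel = sourceLabel)
}

## Minimal RIFF/WAVE reader: integer PCM (8/16/24/32 bit) and IEEE float
## (32/64 bit). 8-bit WAV is unsigned by convention; wider widths signed.
.readWavFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("unreadable file (no RIFF header at byte offset 0): ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("unreadable file (no WAVE tag at byte offset 8): ", path)
  fmt <- NULL
  dataRaw <- NULL
  offset <- 12
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      chunk <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = sum(as.integer(chunk[1:2]) * c(1, 256)),
        channels = sum(as.integer(chunk[3:4]) * c(1, 256)),
        rate = sum(as.integer(chunk[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(chunk[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", size)
      if (length(dataRaw) < size)
        stop(sprintf("truncated WAV data chunk at byte offset %d in %s",
                     offset + 8 + length(dataRaw), path))
    } else {
      invisible(readBin(con, "raw", size))
    }
    offset <- offset + 8 + size + (size %% 2)
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  if (is.null(fmt)) stop("unreadable WAV (missing fmt chunk): ", path)
  if (is.null(dataRaw)) stop("unreadable WAV (missing data chunk): ", path)
  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) carries the real format in the
  # extension; not needed for the plain PCM files handled here.
  if (!fmt$audioFormat %in% c(1L, 3L))
    stop("unsupported WAV encoding (audio format tag ", fmt$audioFormat, ")")
  list(fmt = fmt, data = dataRaw)
}

.decodePcm <- function(raw, bits, float = FALSE, endian = "little") {
  if (float) {
    if (!bits %in% c(32, 64)) stop("unsupported float width: ", bits)
    return(readBin(raw, "double", length(raw) %/% (bits / 8),
                   size = bits / 8, endian = endian))
  }
  if (bits == 8) {
    # 8-bit PCM is unsigned, midpoint 128
    as.integer(readBin(raw, "integer", length(raw), size = 1,
                       signed = FALSE)) - 128L
  } else if (bits %in% c(16, 32)) {
    readBin(raw, "integer", length(raw) %/% (bits / 8), size = bits / 8,
            signed = TRUE, endian = endian)
  } else if (bits == 24) {
    n <- length(raw) %/% 3
    b <- matrix(as.integer(raw[seq_len(3 * n)]), nrow = 3)
    if (identical(endian, "big")) b <- b[3:1, , drop = FALSE]
    v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
    ifelse(v >= 8388608, v - 16777216, v)
  } else stop("unsupported integer width: ", bits)
}

#' Read an acoustic signal into an AmplitudeSeries
#'
#' Reads PCM WAV (8/16/24/32-bit integer or 32/64-bit IEEE float) or a
#' headerless raw integer sample file with a declared rate and width.
#' Integer samples are divided by the full-scale magnitude of the declared
#' width (16-bit: 32768) so that samples lie in \eqn{[-1, 1]}; float data
#' are taken as-is. Multichannel WAV is reduced to mono.
#'
#' @param path file to read.
#' @param format `"wav"` (default) or `"raw"` for headerless files.
#' @param rate sampling rate in Hz; required for raw files, ignored for WAV.
#' @param bits integer sample width for raw files (8, 16, 24 or 32).
#' @param endian byte order for raw files (`"little"` or `"big"`).
#' @param channelPolicy `"first"` (default) keeps the first channel,
#'   `"mean"` averages channels.
#' @param normalize divide integer samples by full scale (default `TRUE`).
#' @return an [AmplitudeSeries-class].
#' @export
loadAudio <- function(path, format = c("wav", "raw"), rate = NULL,
                      bits = 16, endian = "little",
                      channelPolicy = c("first", "mean"), normalize = TRUE) {
  format <- match.arg(format)
  channelPolicy <- match.arg(channelPolicy)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "wav") {
    w <- .readWavFile(path)
    float <- w$fmt$audioFormat == 3L
    v <- .decodePcm(w$data, w$fmt$bits, float = float)
    nc <- w$fmt$channels
    if (nc > 1) {
      v <- matrix(v[seq_len((length(v) %/% nc) * nc)], nrow = nc)
      v <- if (channelPolicy == "first") v[1, ] else colMeans(v)
    }
    scale <- if (float || !normalize) 1 else 2^(w$fmt$bits - 1)
    AmplitudeSeries(v / scale, w$fmt$rate, sourceLabel = basename(path),
                    normalized = normalize || float)
  } else {
    if (is.null(rate)) stop("raw input needs a declared rate")
    raw <- readBin(path, "raw", file.size(path))
    v <- .decodePcm(raw, bits, endian = endian)
    if (bits == 8) v <- v + 0  # already centered in .decodePcm
    scale <- if (normalize) 2^(bits - 1) else 1
    AmplitudeSeries(v / scale, rate, sourceLabel = basename(path),
                    normalized = normalize)
  }
}

#' Read a precomputed instantaneous-energy series from text
#'
#' One numeric column (plain text or CSV with a single column, optionally
#' with a header) of \eqn{\epsilon(t)} values.
#'
#' @param path text file with one energy value per line.
#' @param rate sampling rate in Hz the values were recorded at.
#' @return an [EnergySeries-class].
#' @export
loadEnergySeries <- function(path, rate) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  hasHeader <- is.na(suppressWarnings(as.numeric(
    strsplit(first, ",")[[1]][1])))
  v <- read.table(path, header = hasHeader, sep = if (grepl(",", first)) "," else "")
  EnergySeries(v[[1]], rate, sourceLabel = basename(path))
}

#' Instantaneous energy of an amplitude series
#'
#' Computes \eqn{\epsilon(t) = |A(t)|^2} sample by sample: one energy value
#' per audio sample, same rate. The operation is sign-blind.
#'
#' @param a an [AmplitudeSeries-class].
#' @return an [EnergySeries-class] of the same length and rate.
#' @export
energySeries <- function(a) {
  stopifnot(is(a, "AmplitudeSeries"))
  EnergySeries(a@samples^2, a@rate, sourceLabel = a@sourceLabel)
}
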