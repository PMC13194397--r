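# Audio I/O and time-frequency front-end.
#
# The package works on mono 16 kHz PCM16 RIFF WAV throughout. No installed R
# package in this stack reads WAV or computes mel spectrograms, so a minimal
# codec and filterbank live here; both are deliberately strict about format.

SAMPLE_RATE <- 16000L

#' Write a mono PCM16 WAV file
#'
#' Samples are clipped to `[-1, 1]` and quantized to signed 16-bit.
#' @param samples numeric vector in `[-1, 1]`.
#' @param path output file path.
#' @param sampleRate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
writeWav <- function(samples, path, sampleRate = SAMPLE_RATE) {
  pcm <- as.integer(round(clamp(samples, -1, 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM16 WAV file
#'
#' Only uncompressed mono 16-bit files are accepted (the package's own output
#' format); unknown RIFF chunks are skipped.
#' @param path WAV file path.
#' @return list with `samples` (numeric in `[-1, 1]`) and `sampleRate`.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  stopifnot2(identical(riff, "RIFF"), paste("not a RIFF file:", path))
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  stopifnot2(identical(wave, "WAVE"), paste("not a WAVE file:", path))
  fmt <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1, size = 2, endian = "little"),
        channels    = readBin(con, "integer", 1, size = 2, endian = "little"),
        sampleRate  = readBin(con, "integer", 1, size = 4, endian = "little"))
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      fmt$bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size %/% 2L, size = 2, endian = "little",
                     signed = TRUE)
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  stopifnot2(!is.null(fmt) && !is.null(pcm), paste("malformed WAV:", path))
  stopifnot2(fmt$audioFormat == 1L && fmt$channels == 1L && fmt$bits == 16L,
             "only mono PCM16 WAV is supported")
  list(samples = pcm / 32767, sampleRate = fmt$sampleRate)
}

# Hz -> mel (HTK convention) and back
hzToMel <- function(f) 2595 * log10(1 + f / 700)
melToHz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank, rows = mel bins, cols = FFT bins (one-sided)
melFilterbank <- function(nMel, nFft, sampleRate, fMin = 0, fMax = sampleRate / 2) {
  nBins <- nFft %/% 2L + 1L
  freqs <- (0:(nBins - 1L)) * sampleRate / nFft
  pts <- melToHz(seq(hzToMel(fMin), hzToMel(fMax), length.out = nMel + 2L))
  fb <- matrix(0, nMel, nBins)
  for (m in seq_len(nMel)) {
    lo <- pts[m]; mid <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (freqs - lo) / (mid - lo)
    dn <- (hi - freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))

# short-time power spectrogram; columns are frames
stftPower <- function(x, winLength, hopLength, nFft = winLength) {
  n <- length(x)
  stopifnot2(n >= winLength, "waveform shorter than one analysis window")
  nFrames <- (n - winLength) %/% hopLength + 1L
  win <- hannWindow(winLength)
  frames <- matrix(0, nFft, nFrames)
  for (t in seq_len(nFrames)) {
    seg <- x[((t - 1L) * hopLength + 1L):((t - 1L) * hopLength + winLength)]
    frames[seq_len(winLength), t] <- seg * win
  }
  spec <- mvfft(frames)
  Mod(spec[seq_len(nFft %/% 2L + 1L), , drop = FALSE])^2
}

#' Log-mel spectrogram
#'
#' 25 ms Hann window, 10 ms hop, 128 mel bins, natural log with a `1e-6`
#' floor; the grid convention consumed by the classifier and all relevance
#' maps. Frame rate is `sampleRate / hopLength` (100 fps at defaults).
#' @param samples numeric waveform in `[-1, 1]`.
#' @param sampleRate sampling rate in Hz.
#' @param nMel number of mel bins.
#' @param winLength,hopLength analysis window and hop in samples.
#' @return `nMel x T` matrix with attributes `fps`, `winLength`, `hopLength`.
#' @export
logMelSpectrogram <- function(samples, sampleRate = SAMPLE_RATE, nMel = 128L,
                              winLength = 400L, hopLength = 160L) {
  p <- stftPower(samples, winLength, hopLength, nFft = 512L)
  fb <- melFilterbank(nMel, 512L, sampleRate)
  m <- log(fb %*% p + 1e-6)
  attr(m, "fps") <- sampleRate / hopLength
  attr(m, "winLength") <- winLength
  attr(m, "hopLength") <- hopLength
  m
}

# per-frame energy in dBFS (full scale = 1); frame i covers
# [(i-1) * hop, (i-1) * hop + win) samples
frameEnergyDb <- function(samples, winLength, hopLength) {
  n <- length(samples)
  if (n < winLength) return(numeric(0))
  nFrames <- (n - winLength) %/% hopLength + 1L
  e <- numeric(nFrames)
  for (t in seq_len(nFrames)) {
    seg <- samples[((t - 1L) * hopLength + 1L):((t - 1L) * hopLength + winLength)]
    e[t] <- 10 * log10(mean(seg^2) + 1e-12)
  }
  e
}
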