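#' Audio buffer
#'
#' A fixed-rate mono waveform, the unit of audio exchanged between the song
#' synthesizer, the syllable detector and the pitch estimator. Samples are
#' stored as doubles on a nominal full scale of [-1, 1].
#'
#' @param samples Numeric vector of samples in [-1, 1] (values outside are
#'   permitted but will clip on 16-bit export).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `audio_buffer`.
#' @export
audio_buffer <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer: %d samples @ %g Hz (%.1f ms)>\n",
              length(x$samples), x$sample_rate,
              1000 * length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Duration of an audio buffer in seconds
#' @param x An `audio_buffer`.
#' @return Duration in seconds.
#' @export
audio_duration <- function(x) {
  stopifnot(inherits(x, "audio_buffer"))
  length(x$samples) / x$sample_rate
}

#' Concatenate audio buffers
#' @param ... `audio_buffer` objects with identical sample rates.
#' @return A single `audio_buffer`.
#' @export
audio_concat <- function(...) {
  bufs <- list(...)
  if (length(bufs) == 1L && is.list(bufs[[1]]) && !inherits(bufs[[1]], "audio_buffer"))
    bufs <- bufs[[1]]
  rates <- vapply(bufs, function(b) b$sample_rate, numeric(1))
  if (length(unique(rates)) != 1L) stop("sample rates differ")
  audio_buffer(unlist(lapply(bufs, `[[`, "samples"), use.names = FALSE), rates[[1]])
}

#' Silence of a given duration
#' @param duration_s Duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @return An `audio_buffer` of zeros.
#' @export
audio_silence <- function(duration_s, sample_rate) {
  audio_buffer(numeric(round(duration_s * sample_rate)), sample_rate)
}

#' Fraction of signal power inside a frequency band
#'
#' Power is computed from the periodogram of the whole buffer; the band is
#' inclusive at both edges.
#'
#' @param x An `audio_buffer`.
#' @param low_hz,high_hz Band edges in Hz.
#' @return Band power divided by total power; `NA` for a zero-power buffer.
#' @export
band_power_fraction <- function(x, low_hz, high_hz) {
  stopifnot(inherits(x, "audio_buffer"), low_hz < high_hz)
  n <- length(x$samples)
  spec <- Mod(stats::fft(x$samples))^2
  # keep the one-sided spectrum
  half <- spec[seq_len(floor(n / 2) + 1L)]
  freqs <- (seq_along(half) - 1L) * x$sample_rate / n
  total <- sum(half)
  if (total == 0) return(NA_real_)
  sum(half[freqs >= low_hz & freqs <= high_hz]) / total
}

#' Root-mean-square amplitude
#' @param x An `audio_buffer`.
#' @return RMS of the samples.
#' @export
audio_rms <- function(x) {
  stopifnot(inherits(x, "audio_buffer"))
  sqrt(mean(x$samples^2))
}

# ---- WAV I/O (PCM 16-bit mono little-endian) --------------------------------
# Minimal RIFF/WAVE codec for the single format this pipeline emits.

#' Write an audio buffer as a 16-bit PCM mono WAV file
#'
#' Samples are clipped to [-1, 1] and quantized to 16 bits.
#'
#' @param x An `audio_buffer`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "audio_buffer"))
  s <- pmin(pmax(x$samples, -1), 1)
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(x$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(x$sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#' @param path File path.
#' @return An `audio_buffer`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")   # byte rate
      ba_bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit supported")
      remaining <- size - 16L
      if (remaining > 0) readBin(con, raw(), n = remaining)
    } else if (id == "data") {
      if (is.null(sample_rate)) stop("data chunk before fmt chunk")
      pcm <- readBin(con, integer(), n = size %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
      return(audio_buffer(pcm / 32767, sample_rate))
    } else {
      readBin(con, raw(), n = size)
    }
  }
}
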