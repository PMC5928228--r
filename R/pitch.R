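#' Pitch measurement configuration
#'
#' Pitch is measured from a fast Fourier transform of a 6 ms segment placed
#' on a specified portion of the harmonic stack. 6 ms at 40 kHz is 240
#' samples (~167 Hz native bin width); zero-padding plus parabolic peak
#' interpolation refines the estimate to a few Hz. The search band selects
#' one harmonic; the estimate is the refined peak frequency divided by that
#' harmonic's number.
#'
#' @param harmonic_band_hz Search band (low, high) in Hz containing exactly
#'   one harmonic of the target stack.
#' @param harmonic_number Which harmonic the band contains.
#' @param window_ms Measurement window; fixed at 6 ms.
#' @param fft_oversample Zero-padding factor (default 64).
#' @param distortion_lag_ms Maximum lag from window end to stimulus onset
#'   (ms); in [0, 2].
#' @return A `pitch_config` object.
#' @export
pitch_config <- function(harmonic_band_hz, harmonic_number = 1L,
                         window_ms = 6, fft_oversample = 64L,
                         distortion_lag_ms = 2) {
  stopifnot(length(harmonic_band_hz) == 2L,
            harmonic_band_hz[1] > 0, harmonic_band_hz[1] < harmonic_band_hz[2],
            harmonic_number >= 1, fft_oversample >= 1)
  if (window_ms != 6) stop("window_ms is fixed at 6 ms")
  if (distortion_lag_ms < 0 || distortion_lag_ms > 2)
    stop("distortion_lag_ms must be in [0, 2] ms")
  structure(list(window_ms = window_ms,
                 harmonic_band_hz = harmonic_band_hz,
                 harmonic_number = as.integer(harmonic_number),
                 fft_oversample = as.integer(fft_oversample),
                 distortion_lag_ms = distortion_lag_ms),
            class = "pitch_config")
}

#' Measure pitch in a 6 ms window
#'
#' Applies a Hann window, zero-pads by `fft_oversample`, takes the DFT
#' magnitude, finds the largest peak inside the harmonic search band,
#' refines it by parabolic interpolation over the neighboring bins, and
#' divides by the harmonic number. A pure function: same buffer, same
#' answer.
#'
#' @param audio An `audio_buffer` containing the window.
#' @param window_start_s Window start relative to the buffer origin (s); the
#'   whole 6 ms window must lie inside the buffer.
#' @param cfg A `pitch_config`.
#' @return Estimated fundamental frequency (Hz).
#' @export
measure_pitch <- function(audio, window_start_s, cfg) {
  stopifnot(inherits(audio, "audio_buffer"), inherits(cfg, "pitch_config"))
  fs <- audio$sample_rate
  n <- round(cfg$window_ms / 1000 * fs)
  i0 <- round(window_start_s * fs) + 1L
  i1 <- i0 + n - 1L
  if (i0 < 1L || i1 > length(audio$samples))
    stop("pitch window lies outside the audio buffer")
  x <- audio$samples[i0:i1]
  if (sum(x^2) == 0) stop("zero-power pitch window")
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  nfft <- n * cfg$fft_oversample
  mag <- Mod(stats::fft(c(x * hann, numeric(nfft - n))))
  half <- floor(nfft / 2) + 1L
  mag <- mag[seq_len(half)]
  freqs <- (seq_len(half) - 1L) * fs / nfft
  band <- which(freqs >= cfg$harmonic_band_hz[1] &
                freqs <= cfg$harmonic_band_hz[2])
  if (length(band) == 0L) stop("harmonic_band_hz contains no DFT bins")
  if (max(mag[band]) == 0) stop("no spectral power in the harmonic band")
  k <- band[which.max(mag[band])]
  # parabolic refinement over adjacent bins (guard the spectrum edges)
  delta <- 0
  if (k > 1L && k < half) {
    a <- mag[k - 1L]; b <- mag[k]; c <- mag[k + 1L]
    denom <- a - 2 * b + c
    if (denom != 0) delta <- 0.5 * (a - c) / denom
  }
  ((k - 1L) + delta) * fs / nfft / cfg$harmonic_number
}

#' Threshold state for the pitch contingency
#'
#' Holds the threshold in force, the penalized side, and the update history.
#' With the default `direction = "below"` (penalize low-pitch renditions,
#' driving pitch up) the threshold is a ratchet: it only ever moves up.
#'
#' @param threshold_hz Threshold (Hz).
#' @param direction `"below"` or `"above"`: which side of the threshold is
#'   penalized.
#' @param block_size Update cadence in renditions (400).
#' @return A `threshold_state` object.
#' @export
threshold_state <- function(threshold_hz, direction = c("below", "above"),
                            block_size = 400L) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold_hz), threshold_hz > 0, block_size >= 1)
  structure(list(threshold_hz = threshold_hz, direction = direction,
                 block_size = as.integer(block_size),
                 renditions_since_update = 0L,
                 history = data.frame(block = 0L, threshold_hz = threshold_hz)),
            class = "threshold_state")
}

#' @export
print.threshold_state <- function(x, ...) {
  cat(sprintf("<threshold_state: %0.1f Hz, penalize %s, %d updates>\n",
              x$threshold_hz, x$direction, nrow(x$history) - 1L))
  invisible(x)
}

#' Initialize the threshold from the final baseline day
#'
#' The initial feedback threshold is the median target-syllable pitch of the
#' last baseline day (day 5 of a >= 5 day baseline). For an even number of
#' renditions the median is the mean of the central pair.
#'
#' @param baseline_pitches Pitches (Hz) of the final baseline day; non-empty.
#' @param direction Penalized side; default `"below"`.
#' @param block_size Update cadence in renditions.
#' @return A `threshold_state`.
#' @export
initialize_threshold <- function(baseline_pitches,
                                 direction = c("below", "above"),
                                 block_size = 400L) {
  if (length(baseline_pitches) == 0L)
    stop("baseline pitch list is empty")
  threshold_state(stats::median(baseline_pitches), match.arg(direction),
                  block_size)
}

#' Apply the 400-rendition threshold update
#'
#' Every `block_size` renditions (tumbling, non-overlapping blocks) the
#' median of the block is compared with the threshold in force: if it has
#' moved past the threshold in the direction of learning, the threshold
#' ratchets to the median; otherwise it is unchanged. Either way the
#' rendition counter resets and the history is appended.
#'
#' @param state A `threshold_state`.
#' @param last_block Pitches (Hz) of the completed block; length must equal
#'   `state$block_size`.
#' @return The updated `threshold_state`.
#' @export
update_threshold <- function(state, last_block) {
  stopifnot(inherits(state, "threshold_state"))
  if (length(last_block) != state$block_size)
    stop("expected exactly ", state$block_size, " pitches, got ",
         length(last_block))
  med <- stats::median(last_block)
  if ((state$direction == "below" && med > state$threshold_hz) ||
      (state$direction == "above" && med < state$threshold_hz))
    state$threshold_hz <- med
  state$renditions_since_update <- 0L
  state$history <- rbind(state$history,
                         data.frame(block = nrow(state$history),
                                    threshold_hz = state$threshold_hz))
  state
}

#' Hit/escape decision for one rendition
#'
#' With `direction = "below"` a rendition is a hit iff its pitch is strictly
#' below the threshold; a tie at the threshold escapes. Mirrored for
#' `direction = "above"`.
#'
#' @param pitch_hz Measured pitch (Hz).
#' @param state A `threshold_state`.
#' @return `"hit"` or `"escape"`.
#' @export
decide_outcome <- function(pitch_hz, state) {
  stopifnot(inherits(state, "threshold_state"), is.numeric(pitch_hz))
  hit <- if (state$direction == "below") pitch_hz < state$threshold_hz
         else pitch_hz > state$threshold_hz
  if (hit) "hit" else "escape"
}
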