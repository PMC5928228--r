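#' Harmonic-stack syllable specification
#'
#' Describes one syllable as a stack of harmonics of a fundamental, with a
#' trapezoidal amplitude envelope. The stack is the idealized stand-in for a
#' zebra-finch harmonic syllable: all of its "pitch" information is in the
#' fundamental, which varies rendition to rendition.
#'
#' @param fundamental_hz Nominal fundamental frequency (Hz).
#' @param n_harmonics Number of harmonics (including the fundamental).
#' @param duration_ms Syllable duration (ms); must exceed 6 ms so the pitch
#'   measurement window fits inside it.
#' @param envelope Attack/sustain/decay fractions of the duration; must sum
#'   to 1.
#' @param band_limit_hz Upper band limit (Hz): harmonics above it are absent.
#' @param harmonic_rolloff_db Per-harmonic amplitude roll-off in dB (0 gives
#'   equal-amplitude harmonics).
#' @return A `syllable_spec` object.
#' @export
syllable_spec <- function(fundamental_hz, n_harmonics = 8L, duration_ms = 90,
                          envelope = c(attack = 0.1, sustain = 0.8, decay = 0.1),
                          band_limit_hz = 8000, harmonic_rolloff_db = 0) {
  stopifnot(fundamental_hz > 0, n_harmonics >= 1, duration_ms > 6,
            band_limit_hz > 0, length(envelope) == 3L)
  if (abs(sum(envelope) - 1) > 1e-9) stop("envelope fractions must sum to 1")
  if (fundamental_hz * n_harmonics > band_limit_hz)
    stop("fundamental_hz * n_harmonics exceeds band_limit_hz")
  structure(list(fundamental_hz = fundamental_hz,
                 n_harmonics = as.integer(n_harmonics),
                 duration_ms = duration_ms,
                 envelope = envelope,
                 band_limit_hz = band_limit_hz,
                 harmonic_rolloff_db = harmonic_rolloff_db),
            class = "syllable_spec")
}

#' Motif specification
#'
#' An ordered list of syllables with inter-onset intervals, one of which is
#' the conditioning target. The inter-onset interval from the previous
#' syllable to the target is what the detector's IOI mode matches.
#'
#' @param syllables List of `syllable_spec` objects.
#' @param gaps_ms Silent gap after each syllable except the last (ms), all
#'   positive.
#' @param target_index Index of the target syllable.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(syllables, gaps_ms = numeric(0), target_index = 1L) {
  stopifnot(length(syllables) >= 1L,
            all(vapply(syllables, inherits, logical(1), "syllable_spec")),
            length(gaps_ms) == length(syllables) - 1L,
            all(gaps_ms > 0))
  target_index <- as.integer(target_index)
  if (target_index < 1L || target_index > length(syllables))
    stop("target_index must address a syllable in the list")
  structure(list(syllables = syllables, gaps_ms = gaps_ms,
                 target_index = target_index), class = "motif_spec")
}

#' Synthesize one harmonic-stack syllable
#'
#' Returns a buffer whose discrete spectrum concentrates energy at integer
#' multiples of `rendition_pitch_hz`, shaped by the amplitude envelope.
#' Harmonics above the spec's band limit are dropped; a rendition whose stack
#' would exceed the Nyquist frequency is rejected.
#'
#' @param spec A `syllable_spec`.
#' @param rendition_pitch_hz Fundamental for this rendition (Hz).
#' @param sample_rate Sampling rate (Hz); default 40 kHz.
#' @param peak Peak amplitude on the [-1, 1] full scale.
#' @return An `audio_buffer` of `spec$duration_ms`.
#' @export
synthesize_syllable <- function(spec, rendition_pitch_hz, sample_rate = 40000,
                                peak = 0.5) {
  stopifnot(inherits(spec, "syllable_spec"), rendition_pitch_hz > 0)
  if (rendition_pitch_hz * spec$n_harmonics > sample_rate / 2)
    stop("aliasing: rendition pitch times n_harmonics exceeds Nyquist (",
         sample_rate / 2, " Hz)")
  n <- round(spec$duration_ms / 1000 * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  harm <- seq_len(spec$n_harmonics)
  harm <- harm[harm * rendition_pitch_hz <= spec$band_limit_hz]
  if (length(harm) == 0L) stop("no harmonics below band_limit_hz")
  amps <- 10^(-spec$harmonic_rolloff_db * (harm - 1L) / 20)
  # outer() keeps this fully vectorized: n x n_harmonics
  wave <- as.numeric(sin(outer(t, harm * rendition_pitch_hz * 2 * pi)) %*% amps)

  env <- .trapezoid_envelope(n, spec$envelope)
  wave <- wave * env
  m <- max(abs(wave))
  if (m > 0) wave <- wave * (peak / m)
  audio_buffer(wave, sample_rate)
}

.trapezoid_envelope <- function(n, fractions) {
  na <- max(1L, round(n * fractions[[1]]))
  nd <- max(1L, round(n * fractions[[3]]))
  ns <- n - na - nd
  c(seq(0, 1, length.out = na), rep(1, max(ns, 0L)),
    seq(1, 0, length.out = nd))[seq_len(n)]
}

#' Generate one day of song with ground truth
#'
#' Lays `n_renditions` motif instances on a silent timeline. Motifs are
#' grouped into bouts; motifs inside a bout are separated by short gaps and
#' bouts by silent gaps of at least 2 s, so the singing-state rule (1 s of
#' silence on either side) groups a bout into one singing epoch. Each
#' rendition's target-syllable fundamental is drawn from the vocal agent's
#' current Gaussian pitch distribution (no within-day learning here: this
#' generator emulates an open-loop recording day; the closed loop lives in
#' the session runner).
#'
#' All onset/offset times in the ground-truth log are taken from the sample
#' grid of the assembled audio, so log and audio agree to within one sample.
#'
#' @param motif A `motif_spec`.
#' @param vocal A `vocal_agent` (see [vocal_agent()]).
#' @param n_renditions Number of motif renditions (>= 1).
#' @param seed Integer seed; identical seed reproduces the audio bit for bit.
#' @param sample_rate Sampling rate (Hz).
#' @param motifs_per_bout Maximum motifs per bout (bout sizes drawn uniformly
#'   from 1..motifs_per_bout).
#' @param intra_bout_gap_s Gap between motifs within a bout (s).
#' @param inter_bout_gap_s Silent gap between bouts (s), always >= 2 s.
#' @return A list with `audio` (an `audio_buffer`), `truth` (tibble of
#'   per-rendition target onset/offset/pitch) and `syllables` (tibble of all
#'   syllable onsets/offsets for detector validation).
#' @export
generate_song_day <- function(motif, vocal, n_renditions, seed,
                              sample_rate = 40000, motifs_per_bout = 3L,
                              intra_bout_gap_s = 0.5, inter_bout_gap_s = 2.5) {
  stopifnot(inherits(motif, "motif_spec"), inherits(vocal, "vocal_agent"),
            n_renditions >= 1, inter_bout_gap_s >= 2)
  with_stream_seed(seed, {
    pitches <- stats::rnorm(n_renditions, vocal$pitch_mean_hz, vocal$pitch_sd_hz)
    bout_sizes <- sample.int(motifs_per_bout, n_renditions, replace = TRUE)
    bout_of <- rep(seq_along(bout_sizes), bout_sizes)[seq_len(n_renditions)]

    pieces <- vector("list", 2L * n_renditions + 1L)
    truth_rows <- vector("list", n_renditions)
    syl_rows <- vector("list", n_renditions)
    pieces[[1]] <- audio_silence(inter_bout_gap_s, sample_rate)
    n_cursor <- length(pieces[[1]]$samples)
    k <- 1L
    for (r in seq_len(n_renditions)) {
      motif_audio <- vector("list", 2L * length(motif$syllables) - 1L)
      onsets <- offsets <- numeric(length(motif$syllables))
      j <- 0L
      n_local <- n_cursor
      for (i in seq_along(motif$syllables)) {
        sp <- motif$syllables[[i]]
        pitch_i <- if (i == motif$target_index) pitches[r] else sp$fundamental_hz
        buf <- synthesize_syllable(sp, pitch_i, sample_rate)
        onsets[i] <- n_local / sample_rate
        n_local <- n_local + length(buf$samples)
        offsets[i] <- n_local / sample_rate
        j <- j + 1L; motif_audio[[j]] <- buf
        if (i < length(motif$syllables)) {
          gap <- audio_silence(motif$gaps_ms[i] / 1000, sample_rate)
          n_local <- n_local + length(gap$samples)
          j <- j + 1L; motif_audio[[j]] <- gap
        }
      }
      k <- k + 1L
      pieces[[k]] <- audio_concat(motif_audio[seq_len(j)])
      n_cursor <- n_local
      ti <- motif$target_index
      truth_rows[[r]] <- data.frame(rendition = r,
                                    onset_s = onsets[ti], offset_s = offsets[ti],
                                    pitch_hz = pitches[r])
      syl_rows[[r]] <- data.frame(rendition = r, syllable = seq_along(onsets),
                                  onset_s = onsets, offset_s = offsets,
                                  is_target = seq_along(onsets) == ti)
      gap_s <- if (r < n_renditions && bout_of[r + 1L] == bout_of[r])
        intra_bout_gap_s else inter_bout_gap_s
      gap <- audio_silence(gap_s, sample_rate)
      n_cursor <- n_cursor + length(gap$samples)
      k <- k + 1L
      pieces[[k]] <- gap
    }
    list(audio = audio_concat(pieces[seq_len(k)]),
         truth = tibble::as_tibble(do.call(rbind, truth_rows)),
         syllables = tibble::as_tibble(do.call(rbind, syl_rows)))
  })
}
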