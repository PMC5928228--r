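#' Detector configuration
#'
#' Parameters for amplitude-based syllable segmentation and for the two
#' target-identification modes: matching a unique spectral feature of the
#' syllable preceding the target (band-pass power ratio) or matching a
#' unique inter-onset interval from the previous syllable's onset to the
#' target's onset. A programmable delay then places the pitch-measurement
#' window on the targeted part of the harmonic stack; the hardware the
#' pipeline emulates supported delays of 10-200 ms, enforced here at
#' configuration time.
#'
#' @param amp_threshold Segmentation onset threshold as a linear amplitude
#'   fraction of full scale (applied to the 2 ms moving-RMS envelope).
#' @param min_syllable_ms Minimum segment duration (ms); shorter segments are
#'   discarded.
#' @param min_gap_ms Minimum silent gap (ms); segments separated by less are
#'   merged.
#' @param mode `"spectral_feature"` or `"inter_onset_interval"`.
#' @param feature_band_hz Band (low, high) in Hz for the spectral feature.
#' @param feature_ratio_threshold Minimum in-band power ratio for a match.
#' @param ioi_target_ms Target inter-onset interval (ms).
#' @param ioi_tolerance_ms IOI tolerance (ms), inclusive at the boundary.
#' @param trigger_delay_ms Delay from the detection timestamp to the start of
#'   the 6 ms pitch window (ms); must lie in [10, 200].
#' @return A `detector_config` object.
#' @export
detector_config <- function(amp_threshold = 0.05, min_syllable_ms = 15,
                            min_gap_ms = 8,
                            mode = c("spectral_feature", "inter_onset_interval"),
                            feature_band_hz = NULL,
                            feature_ratio_threshold = 0.1,
                            ioi_target_ms = NULL, ioi_tolerance_ms = 5,
                            trigger_delay_ms = 50) {
  mode <- match.arg(mode)
  if (trigger_delay_ms < 10 || trigger_delay_ms > 200)
    stop("trigger_delay_ms must be in [10, 200] ms")
  stopifnot(amp_threshold > 0, amp_threshold < 1, min_syllable_ms > 0,
            min_gap_ms > 0, ioi_tolerance_ms > 0)
  if (!is.null(feature_band_hz))
    stopifnot(length(feature_band_hz) == 2L, feature_band_hz[1] > 0,
              feature_band_hz[1] < feature_band_hz[2])
  structure(list(amp_threshold = amp_threshold,
                 min_syllable_ms = min_syllable_ms, min_gap_ms = min_gap_ms,
                 mode = mode, feature_band_hz = feature_band_hz,
                 feature_ratio_threshold = feature_ratio_threshold,
                 ioi_target_ms = ioi_target_ms,
                 ioi_tolerance_ms = ioi_tolerance_ms,
                 trigger_delay_ms = trigger_delay_ms),
            class = "detector_config")
}

# Moving-RMS amplitude envelope over a 2 ms window, DC removed first so
# segmentation is insensitive to offset.
amplitude_envelope <- function(x, window_ms = 2) {
  s <- x$samples - mean(x$samples)
  w <- max(1L, round(window_ms / 1000 * x$sample_rate))
  # centered moving average of the squared signal via filter()
  ma <- stats::filter(s^2, rep(1 / w, w), sides = 2)
  ma[is.na(ma)] <- 0
  sqrt(pmax(as.numeric(ma), 0))
}

#' Segment syllables by amplitude
#'
#' Rectify-smooth-threshold with hysteresis: a segment opens where the 2 ms
#' moving-RMS envelope crosses `amp_threshold` and closes where it falls
#' below 0.8 x `amp_threshold`. Segments closer than `min_gap_ms` are merged,
#' then segments shorter than `min_syllable_ms` are discarded. Silent or
#' empty audio yields an empty table, not an error.
#'
#' @param audio An `audio_buffer`.
#' @param cfg A `detector_config`.
#' @return A tibble of segments (onset_s, offset_s, peak_amplitude), in time
#'   order and non-overlapping.
#' @export
segment_syllables <- function(audio, cfg) {
  stopifnot(inherits(audio, "audio_buffer"), inherits(cfg, "detector_config"))
  empty <- tibble::tibble(onset_s = numeric(0), offset_s = numeric(0),
                          peak_amplitude = numeric(0))
  if (length(audio$samples) == 0L) return(empty)
  env <- amplitude_envelope(audio)
  lo <- 0.8 * cfg$amp_threshold
  above_lo <- env >= lo
  if (!any(above_lo)) return(empty)
  # candidate regions: runs above the low (hysteresis) threshold that reach
  # the high threshold at least once
  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  reached <- vapply(seq_along(starts), function(i)
    any(env[starts[i]:ends[i]] >= cfg$amp_threshold), logical(1))
  starts <- starts[reached]; ends <- ends[reached]
  if (length(starts) == 0L) return(empty)

  # merge gaps shorter than min_gap_ms
  min_gap <- cfg$min_gap_ms / 1000 * audio$sample_rate
  if (length(starts) > 1L) {
    gaps <- starts[-1L] - ends[-length(ends)] - 1L
    open <- c(TRUE, gaps >= min_gap)
    grp <- cumsum(open)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  onset <- (starts - 1L) / audio$sample_rate
  offset <- ends / audio$sample_rate
  peak <- vapply(seq_along(starts), function(i)
    max(env[starts[i]:ends[i]]), numeric(1))
  keep <- (offset - onset) * 1000 >= cfg$min_syllable_ms
  tibble::tibble(onset_s = unname(onset[keep]), offset_s = unname(offset[keep]),
                 peak_amplitude = unname(peak[keep]))
}

#' Match a spectral feature in a segment
#'
#' Band-pass filters the segment with a zero-phase order-4 Butterworth filter
#' and compares the filtered power to the segment's total power. A pure
#' function of its inputs; a zero-power segment never matches.
#'
#' @param segment_audio An `audio_buffer` holding one segment.
#' @param cfg A `detector_config` with `feature_band_hz` set.
#' @return `TRUE` iff in-band power / total power >= the configured ratio.
#' @export
match_spectral_feature <- function(segment_audio, cfg) {
  stopifnot(inherits(segment_audio, "audio_buffer"),
            inherits(cfg, "detector_config"),
            !is.null(cfg$feature_band_hz))
  x <- segment_audio$samples
  if (length(x) == 0L) return(FALSE)
  total <- sum(x^2)
  if (total == 0) return(FALSE)
  nyq <- segment_audio$sample_rate / 2
  if (cfg$feature_band_hz[2] >= nyq)
    stop("feature_band_hz must lie below the Nyquist frequency")
  bf <- signal::butter(4, cfg$feature_band_hz / nyq, type = "pass")
  y <- signal::filtfilt(bf, x)
  sum(y^2) / total >= cfg$feature_ratio_threshold
}

#' Match an inter-onset interval
#'
#' @param prev_onset_s,this_onset_s Onset times (s) of the previous and the
#'   candidate target syllable; the candidate must come later.
#' @param cfg A `detector_config` with `ioi_target_ms` set.
#' @return `TRUE` iff the interval is within `ioi_tolerance_ms` of
#'   `ioi_target_ms` (inclusive at the boundary).
#' @export
match_ioi <- function(prev_onset_s, this_onset_s, cfg) {
  stopifnot(inherits(cfg, "detector_config"), !is.null(cfg$ioi_target_ms),
            this_onset_s > prev_onset_s)
  abs((this_onset_s - prev_onset_s) * 1000 - cfg$ioi_target_ms) <=
    cfg$ioi_tolerance_ms
}

#' Start of the pitch window implied by a detection
#'
#' @param detection_time_s Detection timestamp (s): the matched feature
#'   segment's offset in spectral mode, the target syllable's onset in IOI
#'   mode.
#' @param cfg A `detector_config` (its delay was validated at load time).
#' @return `detection_time_s + trigger_delay_ms/1000`, the start of the 6 ms
#'   pitch window.
#' @export
schedule_target_window <- function(detection_time_s, cfg) {
  stopifnot(inherits(cfg, "detector_config"))
  detection_time_s + cfg$trigger_delay_ms / 1000
}

#' End-to-end target detection on a recorded buffer
#'
#' Runs segmentation and then, per the configured mode, identifies target
#' renditions: in spectral mode a segment whose feature band matches flags
#' the *next* segment as the target and the detection timestamp is the
#' matched segment's offset; in IOI mode each consecutive onset pair is
#' tested and the detection timestamp is the target's onset. Each detection
#' schedules a pitch window after the configured delay.
#'
#' @param audio An `audio_buffer` (a recorded day or bout).
#' @param cfg A `detector_config`.
#' @return A tibble (detection_s, target_onset_s, window_start_s), one row
#'   per triggered target.
#' @export
detect_targets <- function(audio, cfg) {
  segs <- segment_syllables(audio, cfg)
  out <- tibble::tibble(detection_s = numeric(0), target_onset_s = numeric(0),
                        window_start_s = numeric(0))
  if (nrow(segs) < 2L) return(out)
  hit_rows <- integer(0); det <- numeric(0)
  if (cfg$mode == "spectral_feature") {
    for (i in seq_len(nrow(segs) - 1L)) {
      i0 <- round(segs$onset_s[i] * audio$sample_rate) + 1L
      i1 <- round(segs$offset_s[i] * audio$sample_rate)
      piece <- audio_buffer(audio$samples[i0:i1], audio$sample_rate)
      if (match_spectral_feature(piece, cfg)) {
        hit_rows <- c(hit_rows, i + 1L)
        det <- c(det, segs$offset_s[i])
      }
    }
  } else {
    for (i in seq_len(nrow(segs) - 1L)) {
      if (match_ioi(segs$onset_s[i], segs$onset_s[i + 1L], cfg)) {
        hit_rows <- c(hit_rows, i + 1L)
        det <- c(det, segs$onset_s[i + 1L])
      }
    }
  }
  tibble::tibble(detection_s = det,
                 target_onset_s = segs$onset_s[hit_rows],
                 window_start_s = schedule_target_window(det, cfg))
}
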