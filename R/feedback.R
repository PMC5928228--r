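#' Stimulus specification
#'
#' Both reinforcers last exactly 75 ms. The noise burst is a band-limited
#' broadband sound (1.5-8 kHz, the spectral range of zebra finch song)
#' played at a calibrated level; the strobe is a 5 ms LED-on / 65 ms all-off
#' / 5 ms LED-on pattern.
#'
#' @param kind `"noise"` or `"strobe"`.
#' @param duration_ms Stimulus duration; 75 ms for both kinds.
#' @param noise_band_hz Band edges (Hz) for the noise burst.
#' @param noise_level_db Playback level in dB; the digital mapping places
#'   88 dB at -20 dBFS RMS (see [render_noise_burst()]).
#' @param strobe_pattern_ms LED on/off/on segment durations (ms); must sum to
#'   `duration_ms`.
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(kind = c("noise", "strobe"), duration_ms = 75,
                          noise_band_hz = c(1500, 8000), noise_level_db = 88,
                          strobe_pattern_ms = c(on = 5, off = 65, on = 5)) {
  kind <- match.arg(kind)
  stopifnot(duration_ms > 0, length(noise_band_hz) == 2L,
            noise_band_hz[1] < noise_band_hz[2])
  if (kind == "strobe" && abs(sum(strobe_pattern_ms) - duration_ms) > 1e-9)
    stop("strobe pattern segments must sum to duration_ms")
  structure(list(kind = kind, duration_ms = duration_ms,
                 noise_band_hz = noise_band_hz,
                 noise_level_db = noise_level_db,
                 strobe_pattern_ms = strobe_pattern_ms),
            class = "stimulus_spec")
}

#' Contingency configuration
#'
#' Exactly one of the four contingencies is active in a session: perch- or
#' pitch-triggered delivery of either the noise burst or the strobe.
#'
#' @param mode One of `"perch_strobe"`, `"perch_noise"`, `"pitch_noise"`,
#'   `"pitch_strobe"`.
#' @param target_perch Stimulated perch (perch modes).
#' @param landing_lag_ms Delay from beam-break landing to the first stimulus
#'   (ms); 1 ms.
#' @param repeat_rate_hz Nominal repeat rate while the perch stays occupied
#'   (Hz); 2.
#' @param repeat_jitter_hz Half-width of the per-interval rate jitter (Hz);
#'   0.25, i.e. each inter-stimulus interval is 1/f with f uniform on
#'   [1.75, 2.25] Hz.
#' @param stimulus A `stimulus_spec`; defaults to the kind implied by `mode`.
#' @return A `contingency_config` object.
#' @export
contingency_config <- function(mode = c("perch_strobe", "perch_noise",
                                        "pitch_noise", "pitch_strobe"),
                               target_perch = 1L, landing_lag_ms = 1,
                               repeat_rate_hz = 2, repeat_jitter_hz = 0.25,
                               stimulus = NULL) {
  mode <- match.arg(mode)
  kind <- if (grepl("noise$", mode)) "noise" else "strobe"
  if (is.null(stimulus)) stimulus <- stimulus_spec(kind)
  stopifnot(inherits(stimulus, "stimulus_spec"), stimulus$kind == kind,
            target_perch %in% c(1L, 2L), landing_lag_ms >= 0,
            repeat_rate_hz > 0, repeat_jitter_hz >= 0,
            repeat_jitter_hz < repeat_rate_hz)
  structure(list(mode = mode, target_perch = as.integer(target_perch),
                 landing_lag_ms = landing_lag_ms,
                 repeat_rate_hz = repeat_rate_hz,
                 repeat_jitter_hz = repeat_jitter_hz,
                 stimulus = stimulus),
            class = "contingency_config")
}

empty_stimulus_log <- function() {
  tibble::tibble(time_s = numeric(0), kind = character(0),
                 cause = character(0), perch_id = integer(0),
                 rendition = integer(0))
}

#' Render the band-limited noise burst
#'
#' The burst is synthesized in the frequency domain: every DFT bin of the
#' 75 ms record inside the band receives unit-variance complex Gaussian
#' weight and every bin outside the band is zero, so the record is exactly
#' band-limited (its own periodogram has zero out-of-band energy). The RMS is
#' scaled by the documented level mapping: the 88 dB calibration point maps
#' to -20 dBFS, i.e. `rms = 10^((noise_level_db - 88)/20) * 0.1`.
#'
#' @param spec A `stimulus_spec` of kind `"noise"`.
#' @param sample_rate Sampling rate (Hz).
#' @param seed Integer seed; identical seed gives an identical buffer.
#' @return A 75 ms `audio_buffer`.
#' @export
render_noise_burst <- function(spec, sample_rate = 40000, seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "noise")
  n <- round(spec$duration_ms / 1000 * sample_rate)
  half <- floor((n - 1) / 2)  # strictly-positive bins below Nyquist
  freqs <- (1:half) * sample_rate / n
  in_band <- freqs >= spec$noise_band_hz[1] & freqs <= spec$noise_band_hz[2]
  with_stream_seed(seed, {
    w <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half))
    w[!in_band] <- 0
    spec_full <- c(0, w, if (n %% 2 == 0) 0, Conj(rev(w)))
    x <- Re(stats::fft(spec_full, inverse = TRUE)) / n
    target_rms <- 10^((spec$noise_level_db - 88) / 20) * 0.1
    x <- x * (target_rms / sqrt(mean(x^2)))
    audio_buffer(x, sample_rate)
  })
}

#' Strobe on/off timeline
#'
#' @param spec A `stimulus_spec` of kind `"strobe"`.
#' @return A data frame of (state, duration_ms): LED on 5 ms, everything off
#'   65 ms, LED on 5 ms; ambient light is restored afterwards. Total 75 ms.
#' @export
strobe_timeline <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "strobe")
  p <- spec$strobe_pattern_ms
  data.frame(state = c("led_on", "all_off", "led_on"),
             duration_ms = as.numeric(p))
}

#' Stimulus times for one occupancy bout under a perch contingency
#'
#' The first stimulus fires `landing_lag_ms` after the beam-break landing;
#' subsequent stimuli repeat at a jittered rate (each inter-onset interval is
#' `1/f` with `f` drawn uniformly from rate +/- jitter) for as long as the
#' perch stays occupied. No onset falls after the departure time. A bout on
#' a non-target perch yields no stimuli.
#'
#' @param bout A list or one-row data frame with `perch_id`, `t_land_s`,
#'   `t_leave_s`.
#' @param cfg A `contingency_config` in a perch mode.
#' @param seed Integer seed for the jitter stream.
#' @return A tibble of stimulus events (time_s, kind, cause, perch_id,
#'   rendition = NA).
#' @export
perch_stimulus_times <- function(bout, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "contingency_config"),
            cfg$mode %in% c("perch_noise", "perch_strobe"),
            bout$t_leave_s >= bout$t_land_s)
  if (bout$perch_id != cfg$target_perch) return(empty_stimulus_log())
  t0 <- bout$t_land_s + cfg$landing_lag_ms / 1000
  if (t0 > bout$t_leave_s) return(empty_stimulus_log())
  dur <- bout$t_leave_s - t0
  lo <- cfg$repeat_rate_hz - cfg$repeat_jitter_hz
  hi <- cfg$repeat_rate_hz + cfg$repeat_jitter_hz
  with_stream_seed(seed, {
    times <- t0
    # draw intervals in chunks until past the departure time
    repeat {
      need <- max(16L, ceiling((bout$t_leave_s - times[length(times)]) * hi) + 4L)
      iv <- 1 / stats::runif(need, lo, hi)
      times <- c(times, times[length(times)] + cumsum(iv))
      if (times[length(times)] > bout$t_leave_s) break
    }
    times <- times[times <= bout$t_leave_s]
    tibble::tibble(time_s = times, kind = cfg$stimulus$kind,
                   cause = c("landing", rep("repeat", length(times) - 1L)),
                   perch_id = as.integer(bout$perch_id),
                   rendition = NA_integer_)
  })
}

#' Stimulus time for one pitch-contingency hit
#'
#' The distortion (or strobe) begins 0-2 ms after the end of the 6 ms pitch
#' measurement window; the lag is drawn uniformly from
#' `[0, pitch_cfg$distortion_lag_ms]`.
#'
#' @param window_start_s Start of the pitch measurement window (s).
#' @param cfg A `contingency_config` in a pitch mode.
#' @param pitch_cfg A `pitch_config`.
#' @param seed Integer seed for the lag draw.
#' @param outcome Outcome of the rendition; calling this on an escape is an
#'   error (stimuli are delivered only on hits).
#' @param rendition Rendition index recorded in the event.
#' @return A one-row tibble stimulus event.
#' @export
pitch_stimulus_time <- function(window_start_s, cfg, pitch_cfg, seed = 1L,
                                outcome = "hit", rendition = NA_integer_) {
  stopifnot(inherits(cfg, "contingency_config"),
            cfg$mode %in% c("pitch_noise", "pitch_strobe"),
            inherits(pitch_cfg, "pitch_config"))
  if (!identical(outcome, "hit"))
    stop("stimulus requested for a non-hit rendition")
  lag_s <- with_stream_seed(seed,
    stats::runif(1, 0, pitch_cfg$distortion_lag_ms / 1000))
  tibble::tibble(time_s = window_start_s + pitch_cfg$window_ms / 1000 + lag_s,
                 kind = cfg$stimulus$kind, cause = "pitch_hit",
                 perch_id = NA_integer_, rendition = as.integer(rendition))
}
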