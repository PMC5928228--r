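# Shared fixtures: a two-syllable motif whose first syllable carries a unique
# spectral feature band, and small default agents/schedules. All fixtures are
# built in code at test time.

fixture_pre_syllable <- function() {
  syllable_spec(2500, n_harmonics = 1L, duration_ms = 60, band_limit_hz = 3000)
}

fixture_target_syllable <- function(f0 = 600) {
  syllable_spec(f0, n_harmonics = 8L, duration_ms = 90)
}

fixture_motif <- function(f0 = 600, gap_ms = 60) {
  motif_spec(list(fixture_pre_syllable(), fixture_target_syllable(f0)),
             gaps_ms = gap_ms, target_index = 2L)
}

fixture_detector <- function(...) {
  detector_config(amp_threshold = 0.03, mode = "spectral_feature",
                  feature_band_hz = c(2300, 2700),
                  feature_ratio_threshold = 0.5, trigger_delay_ms = 100, ...)
}

fixture_pitch_config <- function() {
  pitch_config(harmonic_band_hz = c(1700, 2100), harmonic_number = 3L)
}

# short lights-on day to keep perch simulations fast in unit tests
fixture_schedule <- function(n_days = 1L, lights_off_s = 7200) {
  day_schedule(0, lights_off_s, n_days = n_days)
}

# independent periodogram band-power oracle (plain fft, no package helpers)
oracle_band_power <- function(samples, sample_rate, low, high) {
  n <- length(samples)
  p <- Mod(stats::fft(samples))^2
  half <- p[seq_len(floor(n / 2) + 1L)]
  f <- (seq_along(half) - 1L) * sample_rate / n
  sum(half[f >= low & f <= high]) / sum(half)
}

# independent pitch oracle: argmax of a x64 zero-padded DFT over a band
oracle_peak_freq <- function(samples, sample_rate, low, high, pad = 64L) {
  n <- length(samples)
  mag <- Mod(stats::fft(c(samples, numeric(n * (pad - 1L)))))
  half <- mag[seq_len(floor(n * pad / 2) + 1L)]
  f <- (seq_along(half) - 1L) * sample_rate / (n * pad)
  sel <- f >= low & f <= high
  f[sel][which.max(half[sel])]
}
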