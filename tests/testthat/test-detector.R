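test_that("segmentation recovers ground-truth syllables within 5 ms", {
  day <- generate_song_day(fixture_motif(), vocal_agent(600, 25),
                           n_renditions = 5, seed = 11)
  segs <- segment_syllables(day$audio, fixture_detector())
  expect_equal(nrow(segs), nrow(day$syllables))  # 2 syllables per motif
  err <- sapply(day$syllables$onset_s, function(o) min(abs(segs$onset_s - o)))
  expect_lt(max(err), 0.005)
  # segments are ordered and non-overlapping
  expect_true(all(diff(segs$onset_s) > 0))
  expect_true(all(segs$onset_s[-1] >= segs$offset_s[-nrow(segs)]))
})

test_that("silent audio yields an empty segment table", {
  cfg <- fixture_detector()
  expect_equal(nrow(segment_syllables(audio_silence(1, 40000), cfg)), 0)
  expect_equal(nrow(segment_syllables(audio_buffer(numeric(0), 40000), cfg)), 0)
})

test_that("gaps shorter than min_gap_ms are merged into one segment", {
  tone <- synthesize_syllable(syllable_spec(2000, 1L, duration_ms = 30,
                                            band_limit_hz = 4000), 2000)
  short_gap <- audio_silence(0.004, 40000)  # 4 ms < min_gap 8 ms
  long_gap <- audio_silence(0.05, 40000)
  merged <- audio_concat(list(long_gap, tone, short_gap, tone, long_gap))
  split <- audio_concat(list(long_gap, tone, long_gap, tone, long_gap))
  cfg <- fixture_detector()
  expect_equal(nrow(segment_syllables(merged, cfg)), 1)
  expect_equal(nrow(segment_syllables(split, cfg)), 2)
})

test_that("segmentation is insensitive to DC offset and idempotent", {
  day <- generate_song_day(fixture_motif(), vocal_agent(600, 25),
                           n_renditions = 3, seed = 2)
  cfg <- fixture_detector()
  base <- segment_syllables(day$audio, cfg)
  shifted <- audio_buffer(day$audio$samples + 0.2, 40000)
  expect_equal(segment_syllables(shifted, cfg), base, tolerance = 1e-9)
  expect_equal(segment_syllables(day$audio, cfg), base)
})

test_that("spectral feature match is a band power ratio test", {
  cfg <- detector_config(mode = "spectral_feature",
                         feature_band_hz = c(2000, 3000),
                         feature_ratio_threshold = 0.5)
  tone <- function(f) synthesize_syllable(
    syllable_spec(f, 1L, duration_ms = 50, band_limit_hz = 10000), f)
  expect_true(match_spectral_feature(tone(2500), cfg))
  expect_false(match_spectral_feature(tone(5000), cfg))
  expect_false(match_spectral_feature(audio_silence(0.05, 40000), cfg))
})

test_that("a harmonic stack matches a band holding one of its harmonics", {
  cfg <- detector_config(mode = "spectral_feature",
                         feature_band_hz = c(1700, 1900),
                         feature_ratio_threshold = 0.10)
  stack <- synthesize_syllable(syllable_spec(600, 8L, duration_ms = 80), 600)
  # oracle: the 3rd harmonic's share of band power clears the 10% threshold
  expect_gte(oracle_band_power(stack$samples, 40000, 1700, 1900), 0.10)
  expect_true(match_spectral_feature(stack, cfg))
})

test_that("inter-onset-interval matching is inclusive at the tolerance", {
  cfg <- detector_config(mode = "inter_onset_interval", ioi_target_ms = 120,
                         ioi_tolerance_ms = 5)
  expect_true(match_ioi(0, 0.120, cfg))
  expect_false(match_ioi(0, 0.130, cfg))
  expect_true(match_ioi(0, 0.125, cfg))   # |delta| == tol exactly
  expect_true(match_ioi(0, 0.115, cfg))
})

test_that("trigger delay is bounded at configuration time", {
  expect_equal(schedule_target_window(3.0, fixture_detector()), 3.1)
  expect_no_error(detector_config(trigger_delay_ms = 10))
  expect_no_error(detector_config(trigger_delay_ms = 200))
  expect_error(detector_config(trigger_delay_ms = 250), "10, 200")
  expect_error(detector_config(trigger_delay_ms = 5), "10, 200")
})

test_that("end-to-end targeting hits >= 95% of true targets with no false positives", {
  day <- generate_song_day(fixture_motif(), vocal_agent(600, 25),
                           n_renditions = 40, seed = 31)
  det <- detect_targets(day$audio, fixture_detector())
  matched <- sapply(day$truth$onset_s, function(o)
    any(abs(det$target_onset_s - o) < 0.005))
  expect_gte(mean(matched), 0.95)
  # every detection corresponds to a true target rendition: no false targets
  false_pos <- sapply(det$target_onset_s, function(o)
    !any(abs(day$truth$onset_s - o) < 0.005))
  expect_equal(sum(false_pos), 0)
  # the scheduled 6 ms window falls inside the target syllable
  inside <- sapply(seq_len(nrow(det)), function(i)
    any(det$window_start_s[i] >= day$truth$onset_s &
        det$window_start_s[i] + 0.006 <= day$truth$offset_s))
  expect_true(all(inside))
})

test_that("IOI mode targets the unique pre-target interval", {
  day <- generate_song_day(fixture_motif(gap_ms = 60), vocal_agent(600, 25),
                           n_renditions = 15, seed = 13)
  # IOI = pre syllable (60 ms) + gap (60 ms) = 120 ms onset to onset
  cfg <- detector_config(amp_threshold = 0.03, mode = "inter_onset_interval",
                         ioi_target_ms = 120, ioi_tolerance_ms = 5,
                         trigger_delay_ms = 40)
  det <- detect_targets(day$audio, cfg)
  matched <- sapply(day$truth$onset_s, function(o)
    any(abs(det$target_onset_s - o) < 0.005))
  expect_gte(mean(matched), 0.95)
})
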