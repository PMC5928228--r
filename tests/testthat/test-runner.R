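small_pitch_cfg <- function(mode = "pitch_noise", seed = 3, ...) {
  session_config(
    birds = 1, schedule = day_schedule(0, 43200, n_days = 2),
    contingency = contingency_config(mode),
    vocal = vocal_agent(600, 25, auditory_learning_rate = 0.06),
    n_renditions_per_day = 100, master_seed = seed, ...)
}

test_that("sessions are bit-identical under the same master seed", {
  r1 <- run_session(small_pitch_cfg())
  r2 <- run_session(small_pitch_cfg())
  expect_identical(r1$renditions, r2$renditions)
  expect_identical(r1$stimuli, r2$stimuli)

  p1 <- run_session(session_config(
    birds = 1, schedule = fixture_schedule(n_days = 2),
    contingency = contingency_config("perch_noise"),
    place = place_agent(), master_seed = 5))
  p2 <- run_session(session_config(
    birds = 1, schedule = fixture_schedule(n_days = 2),
    contingency = contingency_config("perch_noise"),
    place = place_agent(), master_seed = 5))
  expect_identical(p1$events, p2$events)
  expect_identical(p1$metrics, p2$metrics)
})

test_that("a session log never mixes perch-cause and pitch-cause events", {
  pitch_res <- run_session(small_pitch_cfg())
  expect_true(all(pitch_res$stimuli$cause == "pitch_hit"))
  perch_res <- run_session(session_config(
    birds = 1, schedule = fixture_schedule(),
    contingency = contingency_config("perch_strobe"),
    place = place_agent(strobe_valence = -1), master_seed = 6))
  expect_true(all(perch_res$stimuli$cause %in% c("landing", "repeat")))
})

test_that("every stimulus traces back to a hit rendition or a target-perch bout", {
  res <- run_session(small_pitch_cfg())
  rend <- res$renditions
  idx_in_day <- stats::ave(seq_len(nrow(rend)),
                           paste(rend$bird_id, rend$day), FUN = seq_along)
  hits <- rend$outcome == "hit"
  expect_equal(nrow(res$stimuli), sum(hits))
  key <- paste(res$stimuli$bird_id, res$stimuli$day, res$stimuli$rendition)
  expect_setequal(key, paste(rend$bird_id, rend$day, idx_in_day)[hits])

  perch_res <- run_session(session_config(
    birds = 1, schedule = fixture_schedule(),
    contingency = contingency_config("perch_noise", target_perch = 1L),
    place = place_agent(), master_seed = 8))
  ev1 <- perch_res$events[perch_res$events$perch_id == 1L, ]
  covered <- vapply(perch_res$stimuli$time_s, function(t)
    any(t >= ev1$t_land_s & t <= ev1$t_leave_s), logical(1))
  expect_true(all(covered))
})

test_that("pitch-contingent strobe with zero visual coupling leaves pitch flat", {
  res <- run_session(small_pitch_cfg(mode = "pitch_strobe", seed = 9))
  expect_equal(res$per_bird$delta_pitch_hz_per_day, 0, tolerance = 6)
  # the agent's mean never moved
  final_day <- max(res$renditions$day)
  expect_lt(abs(mean(res$renditions$true_pitch_hz[res$renditions$day == final_day]) -
                600), 6)
})

test_that("the up phenotype reaches 40 Hz above baseline within 10 days", {
  step <- calibrate_vocal_step(8.8, 25, 400)
  cfg <- session_config(
    birds = 1, schedule = day_schedule(0, 43200, n_days = 10),
    contingency = contingency_config("pitch_noise"),
    vocal = vocal_agent(600, 25, auditory_learning_rate = step),
    n_renditions_per_day = 400, stop_when_shift_hz = 40, master_seed = 17)
  res <- run_session(cfg)
  m <- res$metrics[res$metrics$condition == "pitch_noise", ]
  expect_lte(nrow(m), 10)
  expect_gte(max(m$mean_pitch_hz) - res$per_bird$baseline_mean_hz, 40)
  # the threshold ratcheted monotonically while pitch climbed
  expect_gte(res$per_bird$threshold_final_hz, res$per_bird$baseline_mean_hz)
})

test_that("contingency reversal flips the perch preference", {
  pl <- calibrate_place_agent(place_agent(learning_rate = 0.4), "strobe",
                              target_perch = 1L, landing_p = 0.8,
                              occupancy_p = 0.8)
  flips <- sapply(1:8, function(s) {
    res <- run_session(session_config(
      birds = 1, schedule = fixture_schedule(n_days = 4),
      contingency = contingency_config("perch_strobe", target_perch = 1L),
      place = pl, reversal = list(day = 3L, new_target_perch = 2L),
      master_seed = s))
    m <- res$metrics
    pre <- mean(m$perch1_occupancy[m$day <= 2]) - 0.5
    post <- mean(m$perch1_occupancy[m$day >= 4]) - 0.5
    c(pre = pre, post = post)
  })
  expect_true(all(flips["pre", ] < 0))      # avoid strobed perch 1
  expect_gt(mean(flips["post", ] > 0), 0.7) # prefer perch 1 after reversal
})

test_that("lights-on time is conserved across perch, off-perch and singing splits", {
  res <- run_session(session_config(
    birds = 1, schedule = fixture_schedule(),
    contingency = contingency_config("perch_noise"),
    place = place_agent(), master_seed = 23))
  ev <- res$events
  on_perch <- sum(ev$t_leave_s - ev$t_land_s)
  expect_lte(on_perch, 7200)
  expect_true(all(ev$t_land_s[-1] >= ev$t_leave_s[-nrow(ev)]))  # no overlap
})

test_that("the suite reproduces the four experiments with the right directions", {
  suite <- reproduce_paper_suite(master_seed = 2, birds_perch = 2L,
                                 birds_pitch = 2L,
                                 n_renditions_per_day = 100L,
                                 lights_off_s = 7200)
  expect_named(suite, c("perch_strobe", "perch_noise", "pitch_noise",
                        "pitch_strobe", "anova_strobe", "anova_noise",
                        "summary"))
  s <- suite$summary
  expect_gt(s$value[s$experiment == "perch_strobe"], 0.5)  # avoid strobed P1
  expect_gt(s$value[s$experiment == "perch_noise"], 0.5)   # prefer noisy P1
  expect_gt(s$value[s$experiment == "pitch_noise"],
            abs(s$value[s$experiment == "pitch_strobe"]))
})

test_that("event and rendition logs survive the CSV/JSONL round trip", {
  res <- run_session(session_config(
    birds = 1, schedule = fixture_schedule(),
    contingency = contingency_config("perch_noise"),
    place = place_agent(), master_seed = 31))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(res$events, csv)
  back <- read_events_csv(csv)
  expect_equal(back$t_land_s, res$events$t_land_s, tolerance = 1e-9)
  expect_equal(back$perch_id, res$events$perch_id)

  pres <- run_session(small_pitch_cfg(seed = 33))
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_renditions_jsonl(pres$renditions, jl)
  rback <- read_renditions_jsonl(jl)
  expect_equal(nrow(rback), nrow(pres$renditions))
  expect_equal(rback$pitch_hz, pres$renditions$pitch_hz, tolerance = 1e-7)
})
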