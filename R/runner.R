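#' Session configuration
#'
#' Everything needed to run one closed-loop experiment end to end: how many
#' birds, the day schedule, which of the four contingencies is active, the
#' detector and pitch-measurement settings, the two agents, and the seeding.
#'
#' @param birds Number of birds (each simulated independently with child
#'   seeds).
#' @param schedule A `day_schedule`; its `n_days` is the number of
#'   contingency days (pitch modes additionally run `baseline_days` of
#'   undistorted song first).
#' @param contingency A `contingency_config`.
#' @param pitch A `pitch_config` (pitch modes); `NULL` selects a default
#'   band on the 3rd harmonic of the vocal agent's starting mean.
#' @param detector A `detector_config` or `NULL` (the event-driven loop
#'   measures pitch directly on the per-rendition buffer; the detector path
#'   is exercised by [detect_targets()] on recorded days).
#' @param vocal A `vocal_agent` (pitch modes).
#' @param place A `place_agent` (perch modes).
#' @param target_syllable A `syllable_spec` for the target harmonic stack;
#'   `NULL` builds one from the vocal agent's starting mean.
#' @param baseline_days Baseline days before any pitch contingency; >= 5.
#' @param n_renditions_per_day Target-syllable renditions per day.
#' @param reversal `NULL`, or `list(day =, new_target_perch =)`; perch modes
#'   only.
#' @param stop_when_shift_hz If non-`NULL` (pitch modes), stop after the
#'   first contingency day whose mean pitch is at least this far above
#'   baseline (the 40 Hz session-termination rule).
#' @param song_bouts_per_day,song_bout_s Singing epochs per day and their
#'   mean duration (s), used to build the singing-state track in perch
#'   modes.
#' @param master_seed Master seed; all per-bird/per-day randomness derives
#'   from it.
#' @return A `session_config` object.
#' @export
session_config <- function(birds = 1L, schedule = day_schedule(n_days = 4L),
                           contingency = contingency_config("pitch_noise"),
                           pitch = NULL, detector = NULL,
                           vocal = vocal_agent(), place = place_agent(),
                           target_syllable = NULL, baseline_days = 5L,
                           n_renditions_per_day = 400L, reversal = NULL,
                           stop_when_shift_hz = NULL,
                           song_bouts_per_day = 60L, song_bout_s = 6,
                           master_seed = 1L) {
  stopifnot(birds >= 1, inherits(schedule, "day_schedule"),
            inherits(contingency, "contingency_config"))
  pitch_mode <- grepl("^pitch_", contingency$mode)
  if (pitch_mode && baseline_days < 5)
    stop("pitch contingencies require a baseline of at least 5 days")
  if (!is.null(reversal)) {
    if (pitch_mode) stop("contingency reversal applies to perch modes only")
    stopifnot(is.list(reversal), reversal$day >= 2,
              reversal$new_target_perch %in% c(1L, 2L))
  }
  if (is.null(target_syllable))
    target_syllable <- syllable_spec(vocal$pitch_mean_hz)
  if (is.null(pitch) && pitch_mode) {
    m0 <- vocal$pitch_mean_hz
    pitch <- pitch_config(harmonic_band_hz = c(3 * m0 - 100, 3 * m0 + 300),
                          harmonic_number = 3L)
  }
  structure(list(birds = as.integer(birds), schedule = schedule,
                 contingency = contingency, pitch = pitch,
                 detector = detector, vocal = vocal, place = place,
                 target_syllable = target_syllable,
                 baseline_days = as.integer(baseline_days),
                 n_renditions_per_day = as.integer(n_renditions_per_day),
                 reversal = reversal, stop_when_shift_hz = stop_when_shift_hz,
                 song_bouts_per_day = as.integer(song_bouts_per_day),
                 song_bout_s = song_bout_s,
                 master_seed = as.integer(master_seed)),
            class = "session_config")
}

#' Run one closed-loop session
#'
#' Dispatches on the contingency mode. Pitch modes run the per-rendition
#' loop: synthesize the target harmonic stack at the agent's drawn pitch,
#' measure pitch on the 6 ms window through the FFT path, decide hit/escape
#' against the ratcheting threshold, deliver the stimulus on hits, update
#' the vocal agent, and ratchet the threshold every 400 renditions. Perch
#' modes run the place agent day by day with stimulus delivery and
#' accumulator updates, honoring any contingency reversal. Everything is
#' deterministic under the master seed.
#'
#' @param cfg A `session_config`.
#' @return A `session_result`: a list with `config`, `renditions`, `events`,
#'   `stimuli`, `metrics` (per bird-day tibble), and `per_bird` summaries.
#' @export
run_session <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  res <- if (grepl("^pitch_", cfg$contingency$mode)) run_pitch_session(cfg)
         else run_perch_session(cfg)
  structure(res, class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result: %s, %d bird(s), %d metric rows>\n",
              x$config$contingency$mode, x$config$birds, nrow(x$metrics)))
  invisible(x)
}

# ---- pitch-contingent session ----------------------------------------------

run_pitch_session <- function(cfg) {
  stim_kind <- cfg$contingency$stimulus$kind
  sched <- cfg$schedule
  n_per_day <- cfg$n_renditions_per_day
  lights_len <- sched$lights_off_s - sched$lights_on_s
  all_rend <- list(); all_stim <- list(); per_bird <- list()

  for (bird in seq_len(cfg$birds)) {
    vocal <- cfg$vocal
    rend_rows <- list(); stim_rows <- list()
    # --- baseline: undistorted song; the last day's measured pitches set the
    # initial threshold
    for (d in seq_len(cfg$baseline_days)) {
      seed_d <- derive_seed(cfg$master_seed, "pitch", bird, d)
      true_p <- with_stream_seed(seed_d,
        stats::rnorm(n_per_day, vocal$pitch_mean_hz, vocal$pitch_sd_hz))
      measured <- if (d == cfg$baseline_days)
        measure_rendition_pitches(cfg, true_p) else true_p
      rend_rows[[d]] <- tibble::tibble(
        bird_id = bird, day = d,
        time_s = sched$lights_on_s + (seq_len(n_per_day) - 0.5) *
          lights_len / n_per_day,
        pitch_hz = measured, true_pitch_hz = true_p,
        threshold_hz = NA_real_, outcome = "none", stimulus = "none")
      vocal$pitch_mean_hz <- vocal$pitch_mean_hz + vocal$daily_drift_hz
    }
    baseline_mean <- mean(rend_rows[[cfg$baseline_days]]$pitch_hz)
    thr <- initialize_threshold(rend_rows[[cfg$baseline_days]]$pitch_hz,
                                block_size = 400L)

    # --- contingency days
    block <- numeric(0)
    for (k in seq_len(sched$n_days)) {
      d <- cfg$baseline_days + k
      seed_d <- derive_seed(cfg$master_seed, "pitch", bird, d)
      true_p <- numeric(n_per_day); meas <- numeric(n_per_day)
      thr_log <- numeric(n_per_day); out <- character(n_per_day)
      t_r <- sched$lights_on_s + (seq_len(n_per_day) - 0.5) *
        lights_len / n_per_day
      draws <- with_stream_seed(seed_d, stats::rnorm(n_per_day))
      for (r in seq_len(n_per_day)) {
        true_p[r] <- vocal$pitch_mean_hz + vocal$pitch_sd_hz * draws[r]
        meas[r] <- measure_one_pitch(cfg, true_p[r])
        thr_log[r] <- thr$threshold_hz
        out[r] <- decide_outcome(meas[r], thr)
        if (out[r] == "hit") {
          win_start <- t_r[r]  # nominal window position on the session clock
          ev <- pitch_stimulus_time(win_start, cfg$contingency, cfg$pitch,
                                    seed = derive_seed(seed_d, "lag", r),
                                    rendition = r)
          ev$bird_id <- bird; ev$day <- d
          stim_rows[[length(stim_rows) + 1L]] <- ev
          vocal <- vocal_update(vocal, meas[r], "hit", stim_kind,
                                thr$direction)
        }
        block <- c(block, meas[r])
        if (length(block) == thr$block_size) {
          thr <- update_threshold(thr, block)
          block <- numeric(0)
        }
      }
      rend_rows[[d]] <- tibble::tibble(
        bird_id = bird, day = d, time_s = t_r, pitch_hz = meas,
        true_pitch_hz = true_p, threshold_hz = thr_log, outcome = out,
        stimulus = ifelse(out == "hit", stim_kind, "none"))
      vocal$pitch_mean_hz <- vocal$pitch_mean_hz + vocal$daily_drift_hz
      if (!is.null(cfg$stop_when_shift_hz) &&
          mean(meas) >= baseline_mean + cfg$stop_when_shift_hz) break
    }
    rend <- do.call(rbind, rend_rows)
    all_rend[[bird]] <- rend
    if (length(stim_rows)) all_stim[[bird]] <- do.call(rbind, stim_rows)
    contingency_rend <- rend[rend$day > cfg$baseline_days, , drop = FALSE]
    per_bird[[bird]] <- tibble::tibble(
      bird_id = bird, baseline_mean_hz = baseline_mean,
      final_mean_hz = mean(rend$pitch_hz[rend$day == max(rend$day)]),
      delta_pitch_hz_per_day = daily_pitch_change(contingency_rend),
      threshold_final_hz = thr$threshold_hz)
  }

  renditions <- tibble::as_tibble(do.call(rbind, all_rend))
  metrics <- make_pitch_metrics(renditions, cfg)
  list(config = cfg, renditions = renditions,
       events = NULL,
       stimuli = if (length(all_stim))
         tibble::as_tibble(do.call(rbind, all_stim)) else empty_stimulus_log(),
       metrics = metrics,
       per_bird = tibble::as_tibble(do.call(rbind, per_bird)))
}

# DSP path for a vector of renditions (used for the final baseline day)
measure_rendition_pitches <- function(cfg, true_pitches) {
  vapply(true_pitches, function(p) measure_one_pitch(cfg, p), numeric(1))
}

# synthesize the target stack at the drawn pitch and measure it through the
# 6 ms FFT path, window centered on the syllable
measure_one_pitch <- function(cfg, true_pitch) {
  buf <- synthesize_syllable(cfg$target_syllable, true_pitch)
  win <- (cfg$target_syllable$duration_ms / 2 - cfg$pitch$window_ms / 2) / 1000
  measure_pitch(buf, win, cfg$pitch)
}

make_pitch_metrics <- function(renditions, cfg) {
  rows <- lapply(unique(renditions$bird_id), function(b) {
    rb <- renditions[renditions$bird_id == b, , drop = FALSE]
    days <- sort(unique(rb$day))
    tibble::tibble(
      bird_id = b, day = days,
      condition = ifelse(days <= cfg$baseline_days, "baseline",
                         cfg$contingency$mode),
      mean_pitch_hz = vapply(days, function(d)
        mean(rb$pitch_hz[rb$day == d]), numeric(1)),
      hit_fraction = vapply(days, function(d)
        mean(rb$outcome[rb$day == d] == "hit"), numeric(1)))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# ---- perch-contingent session ----------------------------------------------

run_perch_session <- function(cfg) {
  sched <- cfg$schedule
  all_ev <- list(); all_stim <- list(); met_rows <- list()

  for (bird in seq_len(cfg$birds)) {
    place <- cfg$place
    conting <- cfg$contingency
    for (d in seq_len(sched$n_days)) {
      if (!is.null(cfg$reversal) && d >= cfg$reversal$day)
        conting$target_perch <- as.integer(cfg$reversal$new_target_perch)
      day_seed <- derive_seed(cfg$master_seed, "perch", bird, d)
      sim <- simulate_perch_day(place, sched, conting, day_seed,
                                bird_id = bird, day = d)
      place <- sim$place
      all_ev[[length(all_ev) + 1L]] <- sim$events
      if (nrow(sim$stimuli)) all_stim[[length(all_stim) + 1L]] <- sim$stimuli

      track <- make_song_track(cfg, derive_seed(day_seed, "song"))
      split <- split_by_singing(sim$events, track, perch_id = 1L)
      met_rows[[length(met_rows) + 1L]] <- tibble::tibble(
        bird_id = bird, day = d,
        condition = paste0("P", conting$target_perch, "_",
                           conting$stimulus$kind),
        perch1_landing_rate = landing_rate(sim$events, perch_id = 1L),
        perch1_occupancy = occupancy(sim$events, perch_id = 1L),
        singing_occupancy_p1 = split$singing,
        nonsinging_occupancy_p1 = split$non_singing)
    }
  }
  list(config = cfg,
       renditions = NULL,
       events = tibble::as_tibble(do.call(rbind, all_ev)),
       stimuli = if (length(all_stim))
         tibble::as_tibble(do.call(rbind, all_stim)) else empty_stimulus_log(),
       metrics = tibble::as_tibble(do.call(rbind, met_rows)),
       per_bird = NULL)
}

# singing epochs at uniform times through the lights-on day, independent of
# perch position (song location is not modeled; the split analysis under the
# null of no gating then expects singing ~ non-singing occupancy)
make_song_track <- function(cfg, seed) {
  sched <- cfg$schedule
  with_stream_seed(seed, {
    n <- cfg$song_bouts_per_day
    len <- stats::rexp(n, 1 / cfg$song_bout_s)
    start <- sort(stats::runif(n, sched$lights_on_s,
                               sched$lights_off_s - max(len)))
    # treat each singing epoch as one "syllable" run; singing_track() adds
    # the 1 s margins and merges overlaps
    singing_track(start, start + len, sched$lights_on_s, sched$lights_off_s)
  })
}

#' Run the full four-contingency experiment suite
#'
#' Reproduces the structure of the four experiments plus the two
#' singing-split analyses: perch-contingent strobe (with reversal),
#' perch-contingent noise (with reversal), pitch-contingent noise, and
#' pitch-contingent strobe, each from calibrated agents, followed by
#' two-way ANOVAs of occupancy against condition and singing state.
#'
#' @param master_seed Master seed.
#' @param out_dir If non-`NULL`, logs and metric tables are written there
#'   (CSV/JSONL) under one subdirectory per experiment.
#' @param birds_perch,birds_pitch Birds per perch / pitch experiment.
#' @param n_renditions_per_day Renditions per day in pitch modes.
#' @param lights_off_s Lights-off clock time (s); day length scales the
#'   perch simulations.
#' @return A list of `session_result`s (`perch_strobe`, `perch_noise`,
#'   `pitch_noise`, `pitch_strobe`), singing-split ANOVAs
#'   (`anova_strobe`, `anova_noise`) and a `summary` tibble.
#' @export
reproduce_paper_suite <- function(master_seed = 1L, out_dir = NULL,
                                  birds_perch = 6L, birds_pitch = 5L,
                                  n_renditions_per_day = 400L,
                                  lights_off_s = 43200) {
  sched3 <- day_schedule(0, lights_off_s, n_days = 6L)  # 3 + 3 (reversal)
  sched4 <- day_schedule(0, lights_off_s, n_days = 8L)  # 4 + 4 (reversal)

  # perch strobe: avoidance of the strobed perch (preferred = other perch)
  place_s <- calibrate_place_agent(place_agent(), "strobe", target_perch = 1L,
                                   landing_p = 0.813, occupancy_p = 0.737)
  perch_strobe <- run_session(session_config(
    birds = birds_perch, schedule = sched4,
    contingency = contingency_config("perch_strobe", target_perch = 1L),
    place = place_s, reversal = list(day = 5L, new_target_perch = 2L),
    master_seed = derive_seed(master_seed, "suite", 1)))

  # perch noise: preference for the noisy perch
  place_n <- calibrate_place_agent(place_agent(), "noise", target_perch = 1L,
                                   landing_p = 0.86, occupancy_p = 0.86)
  perch_noise <- run_session(session_config(
    birds = birds_perch, schedule = sched3,
    contingency = contingency_config("perch_noise", target_perch = 1L),
    place = place_n, reversal = list(day = 4L, new_target_perch = 2L),
    master_seed = derive_seed(master_seed, "suite", 2)))

  # pitch noise: vocal agent calibrated to the 8.8 Hz/day escape shift
  step <- calibrate_vocal_step(8.8, pitch_sd_hz = 25,
                               n_per_day = n_renditions_per_day)
  pitch_noise <- run_session(session_config(
    birds = birds_pitch, schedule = day_schedule(0, lights_off_s, n_days = 4L),
    contingency = contingency_config("pitch_noise"),
    vocal = vocal_agent(auditory_learning_rate = step),
    n_renditions_per_day = n_renditions_per_day,
    master_seed = derive_seed(master_seed, "suite", 3)))

  # pitch strobe: visual coupling 0 -> null pitch change
  pitch_strobe <- run_session(session_config(
    birds = birds_pitch, schedule = day_schedule(0, lights_off_s, n_days = 4L),
    contingency = contingency_config("pitch_strobe"),
    vocal = vocal_agent(auditory_learning_rate = step,
                        visual_learning_rate = 0),
    n_renditions_per_day = n_renditions_per_day,
    master_seed = derive_seed(master_seed, "suite", 4)))

  anova_strobe <- singing_split_anova(perch_strobe)
  anova_noise <- singing_split_anova(perch_noise)

  summary <- tibble::tibble(
    experiment = c("perch_strobe", "perch_noise", "pitch_noise",
                   "pitch_strobe"),
    birds = c(birds_perch, birds_perch, birds_pitch, birds_pitch),
    key_metric = c("perch-2 occupancy (pre-reversal)",
                   "perch-1 occupancy (pre-reversal)",
                   "daily pitch change (Hz/day)",
                   "daily pitch change (Hz/day)"),
    value = c(
      mean(1 - pre_reversal(perch_strobe)$perch1_occupancy, na.rm = TRUE),
      mean(pre_reversal(perch_noise)$perch1_occupancy, na.rm = TRUE),
      mean(pitch_noise$per_bird$delta_pitch_hz_per_day),
      mean(pitch_strobe$per_bird$delta_pitch_hz_per_day)))

  out <- list(perch_strobe = perch_strobe, perch_noise = perch_noise,
              pitch_noise = pitch_noise, pitch_strobe = pitch_strobe,
              anova_strobe = anova_strobe, anova_noise = anova_noise,
              summary = summary)
  if (!is.null(out_dir)) write_suite(out, out_dir)
  out
}

pre_reversal <- function(res) {
  rev_day <- res$config$reversal$day
  m <- res$metrics
  if (is.null(rev_day)) m else m[m$day < rev_day, , drop = FALSE]
}

# long-format occupancy table (condition x singing state) for the gating
# analysis, one row per bird-day-state
singing_split_anova <- function(res) {
  m <- res$metrics
  long <- rbind(
    data.frame(occupancy = m$singing_occupancy_p1, condition = m$condition,
               singing_state = "singing"),
    data.frame(occupancy = m$nonsinging_occupancy_p1, condition = m$condition,
               singing_state = "non_singing"))
  two_way_anova(long)
}
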