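#' Vocal learning agent
#'
#' A phenomenological model of escape learning on syllable pitch: rendition
#' pitches are Gaussian around a slowly moving mean, and each penalized
#' rendition (a "hit") moves the mean away from the penalized side of the
#' threshold by a fixed step. The step for auditory punishment (noise) and
#' for visual punishment (strobe) are independent; with the visual rate at
#' its default of 0 the pitch distribution is invariant to strobe events —
#' the differential valence wiring under study.
#'
#' @param pitch_mean_hz Current mean of the rendition pitch distribution (Hz).
#' @param pitch_sd_hz Rendition-to-rendition SD (Hz), > 0.
#' @param auditory_learning_rate Mean shift per noise hit (Hz), >= 0.
#' @param visual_learning_rate Mean shift per strobe hit (Hz), >= 0;
#'   default 0.
#' @param daily_drift_hz Deterministic baseline drift per day (Hz/day).
#' @return A `vocal_agent` object.
#' @export
vocal_agent <- function(pitch_mean_hz = 600, pitch_sd_hz = 25,
                        auditory_learning_rate = 0.05,
                        visual_learning_rate = 0, daily_drift_hz = 0) {
  stopifnot(pitch_sd_hz > 0, auditory_learning_rate >= 0,
            visual_learning_rate >= 0)
  structure(list(pitch_mean_hz = pitch_mean_hz, pitch_sd_hz = pitch_sd_hz,
                 auditory_learning_rate = auditory_learning_rate,
                 visual_learning_rate = visual_learning_rate,
                 daily_drift_hz = daily_drift_hz),
            class = "vocal_agent")
}

#' @export
print.vocal_agent <- function(x, ...) {
  cat(sprintf(paste0("<vocal_agent: pitch %0.1f +/- %0.1f Hz, ",
                     "step/hit noise %0.3g Hz, strobe %0.3g Hz>\n"),
              x$pitch_mean_hz, x$pitch_sd_hz,
              x$auditory_learning_rate, x$visual_learning_rate))
  invisible(x)
}

#' Update the vocal agent after one rendition
#'
#' On a hit, the pitch mean moves away from the penalized region: upward when
#' the contingency penalizes the region below the threshold, downward for
#' the mirrored direction. The step is `auditory_learning_rate` for a noise
#' stimulus and `visual_learning_rate` for a strobe stimulus, so strobe hits
#' leave the agent unchanged under the default wiring. Escapes never change
#' the state.
#'
#' @param vocal A `vocal_agent`.
#' @param rendition_pitch Measured pitch of the rendition (Hz); recorded for
#'   the caller's log, not used by the update rule itself.
#' @param outcome `"hit"` or `"escape"`.
#' @param stimulus `"noise"` or `"strobe"`.
#' @param direction Which side of the threshold is penalized (`"below"`
#'   drives pitch up).
#' @return The updated `vocal_agent`.
#' @export
vocal_update <- function(vocal, rendition_pitch, outcome,
                         stimulus = c("noise", "strobe"),
                         direction = c("below", "above")) {
  stopifnot(inherits(vocal, "vocal_agent"))
  outcome <- match.arg(outcome, c("hit", "escape"))
  stimulus <- match.arg(stimulus)
  direction <- match.arg(direction)
  if (outcome == "escape") return(vocal)
  step <- if (stimulus == "noise") vocal$auditory_learning_rate
          else vocal$visual_learning_rate
  sgn <- if (direction == "below") 1 else -1
  vocal$pitch_mean_hz <- vocal$pitch_mean_hz + sgn * step
  vocal
}

#' Calibrate the vocal agent's per-hit step to an expected daily pitch shift
#'
#' Under the closed loop the hit probability is not constant: the threshold
#' ratchets to the previous 400-rendition block's median, so the mean runs
#' ahead of the threshold and hits occur at rate Phi((T - mu)/sigma) < 1/2.
#' This routine finds, by root-finding on the deterministic mean-field
#' dynamics of that loop (mu advances by step * Phi((T - mu)/sigma) per
#' rendition; T ratchets to the block mean of mu at each block boundary), the
#' per-hit step for which the expected mean consecutive-day change in daily
#' mean pitch equals `daily_shift_hz`.
#'
#' @param daily_shift_hz Desired expected daily pitch change (Hz/day).
#' @param pitch_sd_hz Rendition SD (Hz).
#' @param n_per_day Renditions per day.
#' @param n_days Number of contingency days the expectation averages over.
#' @param block_size Threshold update cadence in renditions.
#' @return The per-hit step (Hz) to use as `auditory_learning_rate`.
#' @export
calibrate_vocal_step <- function(daily_shift_hz, pitch_sd_hz = 25,
                                 n_per_day = 400, n_days = 4,
                                 block_size = 400) {
  stopifnot(daily_shift_hz >= 0, pitch_sd_hz > 0, n_per_day >= 1,
            block_size >= 1)
  if (daily_shift_hz == 0) return(0)
  mean_field_shift <- function(step) {
    mu <- 0; thr <- 0
    day_means <- numeric(n_days)
    block <- numeric(block_size); bi <- 0L
    for (d in seq_len(n_days)) {
      trace <- numeric(n_per_day)
      for (n in seq_len(n_per_day)) {
        mu <- mu + step * stats::pnorm((thr - mu) / pitch_sd_hz)
        trace[n] <- mu
        bi <- bi + 1L; block[bi] <- mu
        if (bi == block_size) {
          # mean-field median of the block: the symmetric rendition noise
          # leaves the median at the mean of the drifting means
          med <- mean(block)
          if (med > thr) thr <- med
          bi <- 0L
        }
      }
      day_means[d] <- mean(trace)
    }
    mean(diff(day_means))
  }
  # daily shift is monotone in the step; bracket generously
  hi <- 4 * daily_shift_hz / n_per_day * 10
  while (mean_field_shift(hi) < daily_shift_hz) hi <- hi * 2
  stats::uniroot(function(s) mean_field_shift(s) - daily_shift_hz,
                 lower = 1e-9, upper = hi, tol = 1e-7)$root
}

#' Place (navigation) agent
#'
#' A softmax-choice agent over two test perches with leaky perch-value
#' accumulators. Each delivered stimulus on a perch updates that perch's
#' value by `eta * (valence - leak * value)`, so values converge to the fixed
#' point `valence / leak`. Under the default wiring noise carries positive
#' valence (appetitive to the navigation system) and strobe negative valence
#' (aversive); both are configurable, including sign.
#'
#' @param perch_values Numeric length-2 valence accumulators.
#' @param softmax_temperature Softmax temperature (dimensionless), > 0.
#' @param mean_bout_s Mean occupancy bout duration per perch (s); a scalar is
#'   recycled to both perches.
#' @param mean_offperch_s Mean off-perch interval between bouts (s).
#' @param noise_valence Valence of a noise stimulus (> 0 by default wiring).
#' @param strobe_valence Valence of a strobe stimulus (< 0 by default wiring).
#' @param learning_rate Accumulator step `eta` per delivered stimulus.
#' @param leak Accumulator leak `lambda` (> 0).
#' @param extinction_rate Fractional decay of a perch's value on each landing
#'   there that delivers no stimulus (extinction of the learned association
#'   once the contingency moves away, e.g. after a reversal).
#' @return A `place_agent` object.
#' @export
place_agent <- function(perch_values = c(0, 0), softmax_temperature = 1,
                        mean_bout_s = 30, mean_offperch_s = 30,
                        noise_valence = 1, strobe_valence = -1,
                        learning_rate = 0.2, leak = 1,
                        extinction_rate = 0.05) {
  stopifnot(length(perch_values) == 2L, softmax_temperature > 0,
            all(mean_bout_s > 0), mean_offperch_s > 0,
            learning_rate > 0, leak > 0, learning_rate * leak < 2,
            extinction_rate >= 0, extinction_rate <= 1)
  structure(list(perch_values = perch_values,
                 softmax_temperature = softmax_temperature,
                 mean_bout_s = rep(mean_bout_s, length.out = 2L),
                 mean_offperch_s = mean_offperch_s,
                 noise_valence = noise_valence,
                 strobe_valence = strobe_valence,
                 learning_rate = learning_rate, leak = leak,
                 extinction_rate = extinction_rate),
            class = "place_agent")
}

#' @export
print.place_agent <- function(x, ...) {
  p <- choice_probabilities(x)
  cat(sprintf("<place_agent: values (%0.2f, %0.2f), P(perch1) = %0.3f>\n",
              x$perch_values[1], x$perch_values[2], p[1]))
  invisible(x)
}

#' Perch choice probabilities of a place agent
#'
#' Softmax over the perch values; always sums to 1.
#'
#' @param place A `place_agent`.
#' @return Length-2 probability vector.
#' @export
choice_probabilities <- function(place) {
  stopifnot(inherits(place, "place_agent"))
  z <- place$perch_values / place$softmax_temperature
  e <- exp(z - max(z))
  e / sum(e)
}

# Closed-form leaky accumulator update after n identical stimuli on perch k:
# v <- v*a^n + (valence/leak)*(1 - a^n), a = 1 - eta*leak.
place_absorb_stimuli <- function(place, perch, n_stimuli, valence) {
  if (n_stimuli <= 0) return(place)
  a <- 1 - place$learning_rate * place$leak
  an <- a^n_stimuli
  v <- place$perch_values[perch]
  place$perch_values[perch] <- v * an + (valence / place$leak) * (1 - an)
  place
}

#' Calibrate the place agent to target landing and occupancy probabilities
#'
#' Sets the stimulus valence so the accumulator fixed point yields the
#' requested asymptotic probability of landing on the preferred perch
#' (`v* = valence/leak = temperature * logit(p)` on the stimulated perch,
#' with sign per stimulus kind), and sets the per-perch mean bout durations
#' so that the asymptotic occupancy — `p*b_pref / (p*b_pref + (1-p)*b_other)`
#' — equals the requested occupancy. Landing rate and occupancy therefore
#' decouple exactly as in empirical data where the two differ.
#'
#' @param place A `place_agent` to start from.
#' @param stimulus `"noise"` or `"strobe"`: which valence is being wired.
#' @param target_perch The stimulated perch (1 or 2).
#' @param landing_p Asymptotic probability of choosing the preferred perch
#'   (the stimulated perch for noise, the other perch for strobe).
#' @param occupancy_p Asymptotic occupancy of the preferred perch; defaults
#'   to `landing_p` (equal bout durations).
#' @return The calibrated `place_agent` (values still at their starting
#'   point; learning moves them to the fixed point).
#' @export
calibrate_place_agent <- function(place, stimulus = c("noise", "strobe"),
                                  target_perch = 1L, landing_p,
                                  occupancy_p = landing_p) {
  stopifnot(inherits(place, "place_agent"),
            landing_p > 0, landing_p < 1, occupancy_p > 0, occupancy_p < 1)
  stimulus <- match.arg(stimulus)
  logit <- function(p) log(p / (1 - p))
  dv <- place$softmax_temperature * logit(landing_p)
  # the stimulated perch's value converges to valence/leak; the other stays 0
  if (stimulus == "noise") {
    place$noise_valence <- place$leak * dv      # preferred = stimulated perch
    preferred <- target_perch
  } else {
    place$strobe_valence <- -place$leak * dv    # preferred = other perch
    preferred <- 3L - target_perch
  }
  # bout-duration ratio that maps the landing odds onto the occupancy odds
  r <- (occupancy_p / (1 - occupancy_p)) / (landing_p / (1 - landing_p))
  base <- mean(place$mean_bout_s)
  b <- c(base, base)
  b[preferred] <- base * r
  place$mean_bout_s <- b
  place
}

#' Lights-on/lights-off day schedule
#'
#' @param lights_on_s,lights_off_s Clock times in seconds since day start;
#'   lights on before lights off. No perch events or song occur outside the
#'   lights-on window (birds do not move during lights-off).
#' @param n_days Number of days the schedule repeats.
#' @return A `day_schedule` object.
#' @export
day_schedule <- function(lights_on_s = 0, lights_off_s = 43200, n_days = 1L) {
  stopifnot(lights_on_s < lights_off_s, n_days >= 1)
  structure(list(lights_on_s = lights_on_s, lights_off_s = lights_off_s,
                 n_days = as.integer(n_days)), class = "day_schedule")
}

#' Simulate one day of perch behavior under a contingency
#'
#' Event-driven loop over the lights-on window: off-perch intervals and
#' occupancy bouts are exponential with the agent's means, perch choice is
#' softmax over the current values, and on the stimulated perch the delivered
#' stimuli (landing-triggered plus jittered 2 Hz repeats) update the
#' accumulators. Bouts are truncated at lights-off, so no event intersects
#' the lights-off period. Identical seed reproduces the event stream.
#'
#' @param place A `place_agent`.
#' @param schedule A `day_schedule`.
#' @param contingency A `contingency_config` in a perch mode, or `NULL` for a
#'   stimulus-free (null) day.
#' @param seed Integer seed for this day.
#' @param bird_id,day Identifiers copied into the event log.
#' @return A list: `events` (tibble bird_id, day, perch_id, t_land_s,
#'   t_leave_s), `stimuli` (tibble of delivered `stimulus_event` rows) and
#'   `place`, the updated agent.
#' @export
simulate_perch_day <- function(place, schedule, contingency = NULL, seed,
                               bird_id = 1L, day = 1L) {
  stopifnot(inherits(place, "place_agent"), inherits(schedule, "day_schedule"))
  perch_mode <- !is.null(contingency) &&
    contingency$mode %in% c("perch_noise", "perch_strobe")
  valence <- if (perch_mode && contingency$stimulus$kind == "noise")
    place$noise_valence else place$strobe_valence
  with_stream_seed(seed, {
    t <- schedule$lights_on_s
    events <- list(); stim <- list(); b <- 0L
    while (TRUE) {
      t_land <- t + stats::rexp(1, 1 / place$mean_offperch_s)
      if (t_land >= schedule$lights_off_s) break
      perch <- sample.int(2L, 1L, prob = choice_probabilities(place))
      t_leave <- min(t_land + stats::rexp(1, 1 / place$mean_bout_s[perch]),
                     schedule$lights_off_s)
      b <- b + 1L
      events[[b]] <- data.frame(bird_id = bird_id, day = day, perch_id = perch,
                                t_land_s = t_land, t_leave_s = t_leave)
      delivered <- FALSE
      if (perch_mode && perch == contingency$target_perch) {
        ev <- perch_stimulus_times(
          list(perch_id = perch, t_land_s = t_land, t_leave_s = t_leave),
          contingency, seed = derive_seed(seed, "stim", b))
        if (nrow(ev) > 0) {
          ev$bird_id <- bird_id; ev$day <- day
          stim[[length(stim) + 1L]] <- ev
          place <- place_absorb_stimuli(place, perch, nrow(ev), valence)
          delivered <- TRUE
        }
      }
      # landings without any stimulus extinguish that perch's association
      if (!delivered)
        place$perch_values[perch] <-
          place$perch_values[perch] * (1 - place$extinction_rate)
      t <- t_leave
    }
    if (b == 0L)
      events <- list(data.frame(bird_id = integer(0), day = integer(0),
                                perch_id = integer(0), t_land_s = numeric(0),
                                t_leave_s = numeric(0)))
    list(events = tibble::as_tibble(do.call(rbind, events)),
         stimuli = if (length(stim)) tibble::as_tibble(do.call(rbind, stim))
                   else empty_stimulus_log(),
         place = place)
  })
}
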