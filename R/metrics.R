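#' Clip occupancy bouts to the lights-on window
#'
#' Lights-off (sleep) time is excluded from every behavioral denominator;
#' bouts straddling the boundary are truncated, bouts entirely outside are
#' dropped.
#'
#' @param events Perch-event tibble (perch_id, t_land_s, t_leave_s, ...).
#' @param schedule A `day_schedule`, or `NULL` to leave events unclipped.
#' @return The clipped event tibble.
#' @export
clip_to_lights_on <- function(events, schedule = NULL) {
  if (is.null(schedule)) return(events)
  ev <- events
  ev$t_land_s <- pmax(ev$t_land_s, schedule$lights_on_s)
  ev$t_leave_s <- pmin(ev$t_leave_s, schedule$lights_off_s)
  ev[ev$t_leave_s > ev$t_land_s, , drop = FALSE]
}

#' Perch landing rate
#'
#' Fraction of test-perch landings that were on the given perch, lights-off
#' excluded. A day with no landings yields a missing value, never 0.
#'
#' @param events Perch-event tibble for one bird.
#' @param day Day to evaluate, or `NULL` for all rows.
#' @param perch_id Perch (1 or 2).
#' @param schedule Optional `day_schedule` used to exclude lights-off
#'   landings from externally supplied logs.
#' @return Probability in [0, 1], or `NA` if there were no landings.
#' @export
landing_rate <- function(events, day = NULL, perch_id, schedule = NULL) {
  ev <- events
  if (!is.null(day)) ev <- ev[ev$day == day, , drop = FALSE]
  if (!is.null(schedule))
    ev <- ev[ev$t_land_s >= schedule$lights_on_s &
             ev$t_land_s < schedule$lights_off_s, , drop = FALSE]
  n_total <- nrow(ev)
  if (n_total == 0L) return(NA_real_)
  sum(ev$perch_id == perch_id) / n_total
}

#' Perch occupancy
#'
#' Fraction of test-perch time spent on the given perch, with every bout
#' clipped to the lights-on window. Occupancies of the two perches sum to 1
#' whenever defined; zero total perch time yields a missing value.
#'
#' @inheritParams landing_rate
#' @return Probability in [0, 1], or `NA` if no perch time was recorded.
#' @export
occupancy <- function(events, day = NULL, perch_id, schedule = NULL) {
  ev <- events
  if (!is.null(day)) ev <- ev[ev$day == day, , drop = FALSE]
  ev <- clip_to_lights_on(ev, schedule)
  dur <- ev$t_leave_s - ev$t_land_s
  total <- sum(dur)
  if (total == 0) return(NA_real_)
  sum(dur[ev$perch_id == perch_id]) / total
}

#' Singing-state track for one day
#'
#' The singing state runs from 1 s of silence before a song syllable onset
#' until 1 s of silence after a song syllable offset; syllables separated by
#' less than 2 s of silence therefore belong to one singing epoch. The rest
#' of the lights-on day is non-singing. The returned intervals tile
#' [day_start, day_end] with no overlap.
#'
#' @param onsets,offsets Syllable onset/offset times (s), sorted, equal
#'   length; may be empty (a day with no song).
#' @param day_start,day_end Lights-on window (s).
#' @return A tibble (start_s, end_s, state) with state `"singing"` or
#'   `"non_singing"`.
#' @export
singing_track <- function(onsets, offsets, day_start, day_end) {
  stopifnot(length(onsets) == length(offsets), day_start < day_end)
  if (length(onsets) == 0L)
    return(tibble::tibble(start_s = day_start, end_s = day_end,
                          state = "non_singing"))
  o <- order(onsets)
  onsets <- onsets[o]; offsets <- offsets[o]
  # epochs: split where silence between syllables reaches 2 s
  new_epoch <- c(TRUE, onsets[-1L] - offsets[-length(offsets)] >= 2)
  grp <- cumsum(new_epoch)
  starts <- pmax(tapply(onsets, grp, min) - 1, day_start)
  ends <- pmin(tapply(offsets, grp, max) + 1, day_end)
  # merge any overlap introduced by the 1 s extensions
  keep_s <- numeric(0); keep_e <- numeric(0)
  for (i in seq_along(starts)) {
    if (length(keep_e) > 0L && starts[i] <= keep_e[length(keep_e)]) {
      keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], ends[i])
    } else {
      keep_s <- c(keep_s, starts[i]); keep_e <- c(keep_e, ends[i])
    }
  }
  bounds_s <- c(day_start, as.numeric(rbind(keep_s, keep_e)))
  bounds_e <- c(as.numeric(rbind(keep_s, keep_e)), day_end)
  states <- rep(c("non_singing", "singing"), length.out = length(bounds_s))
  out <- tibble::tibble(start_s = bounds_s, end_s = bounds_e, state = states)
  out[out$end_s > out$start_s, , drop = FALSE]
}

.track_tiles <- function(track) {
  nrow(track) > 0L &&
    all(abs(track$start_s[-1L] - track$end_s[-nrow(track)]) < 1e-9) &&
    all(track$end_s >= track$start_s)
}

#' Occupancy split by singing state
#'
#' Apportions each perch bout's duration to singing and non-singing states by
#' interval intersection with the state track, then computes the perch's
#' occupancy separately within each state. Each state-conditioned occupancy
#' pair over the two perches satisfies complementarity. A state with no
#' perch time yields a missing occupancy.
#'
#' @param events Perch-event tibble for one bird-day (already lights-on
#'   only).
#' @param track A `singing_track()` tibble tiling the day; a non-tiling
#'   track is an error.
#' @param perch_id Perch to report.
#' @return A list with elements `singing` and `non_singing`.
#' @export
split_by_singing <- function(events, track, perch_id) {
  if (!.track_tiles(track))
    stop("singing-state track does not tile the day")
  state_time <- function(state, perch) {
    tr <- track[track$state == state, , drop = FALSE]
    ev <- events[events$perch_id == perch, , drop = FALSE]
    if (nrow(tr) == 0L || nrow(ev) == 0L) return(0)
    # total pairwise interval intersection
    sum(vapply(seq_len(nrow(ev)), function(i) {
      lo <- pmax(ev$t_land_s[i], tr$start_s)
      hi <- pmin(ev$t_leave_s[i], tr$end_s)
      sum(pmax(hi - lo, 0))
    }, numeric(1)))
  }
  one_state <- function(state) {
    on_p <- state_time(state, perch_id)
    total <- on_p + state_time(state, 3L - as.integer(perch_id))
    if (total == 0) NA_real_ else on_p / total
  }
  list(singing = one_state("singing"), non_singing = one_state("non_singing"))
}

#' Average daily pitch change
#'
#' The mean over successive qualifying days of the change in daily mean
#' pitch, expressed per day (differences across a gap of excluded days are
#' divided by the day gap). Days with fewer than `min_renditions` renditions
#' do not qualify; fewer than two qualifying days yields a missing value.
#'
#' @param renditions Rendition tibble with columns `day` and `pitch_hz`.
#' @param min_renditions Minimum renditions for a day to qualify (20).
#' @return Hz per day, or `NA`.
#' @export
daily_pitch_change <- function(renditions, min_renditions = 20L) {
  counts <- table(renditions$day)
  good_days <- as.numeric(names(counts)[counts >= min_renditions])
  if (length(good_days) < 2L) return(NA_real_)
  good_days <- sort(good_days)
  means <- vapply(good_days, function(d)
    mean(renditions$pitch_hz[renditions$day == d]), numeric(1))
  mean(diff(means) / diff(good_days))
}

#' One-sample t test against a null mean
#'
#' Classical two-sided one-sample t test (the workhorse for testing perch
#' probabilities against the equal-occupancy null of 0.5). Zero-variance
#' input is handled explicitly: if every value equals the null the statistic
#' is 0 with p = 1; otherwise the statistic is infinite, p is 0, and the
#' result is flagged degenerate.
#'
#' @param values Numeric sample, n >= 2 (missing values dropped).
#' @param null_mean Null hypothesis mean; default 0.5.
#' @return A list (t, df, p, degenerate).
#' @export
one_sample_t <- function(values, null_mean = 0.5) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 non-missing values")
  if (stats::sd(values) == 0) {
    m <- mean(values)
    if (isTRUE(all.equal(m, null_mean)))
      return(list(t = 0, df = length(values) - 1L, p = 1, degenerate = TRUE))
    return(list(t = sign(m - null_mean) * Inf, df = length(values) - 1L,
                p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = null_mean)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Two-sample t test (unpaired, pooled variance)
#'
#' Used for contingency-reversal comparisons (pre- vs post-reversal
#' probabilities).
#'
#' @param x,y Numeric samples (missing values dropped).
#' @return A list (t, df, p).
#' @export
two_sample_t <- function(x, y) {
  ht <- stats::t.test(x[!is.na(x)], y[!is.na(y)], var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Two-way ANOVA on occupancy
#'
#' Fits `occupancy ~ condition * singing_state` and reports Type II F tests
#' for the two main effects and the interaction (Type II accommodates the
#' unbalanced bird-day designs these experiments produce; for balanced
#' tables it coincides with the classical sums of squares). An empty design
#' cell is an error naming the cell.
#'
#' @param table Data frame with columns `occupancy`, `condition`,
#'   `singing_state` (two levels each).
#' @return A list with per-term entries (F, df1, df2, p) for `condition`,
#'   `singing_state` and `interaction`.
#' @export
two_way_anova <- function(table) {
  stopifnot(all(c("occupancy", "condition", "singing_state") %in%
                names(table)))
  table <- table[!is.na(table$occupancy), , drop = FALSE]
  table$condition <- factor(table$condition)
  table$singing_state <- factor(table$singing_state)
  cells <- base::table(table$condition, table$singing_state)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: condition = ", rownames(cells)[idx[1]],
         ", singing_state = ", colnames(cells)[idx[2]])
  }
  fit <- stats::lm(occupancy ~ condition * singing_state, data = table)
  an <- car::Anova(fit, type = 2)
  df2 <- an["Residuals", "Df"]
  term <- function(row) list(F = an[row, "F value"], df1 = an[row, "Df"],
                             df2 = df2, p = an[row, "Pr(>F)"])
  list(condition = term("condition"),
       singing_state = term("singing_state"),
       interaction = term("condition:singing_state"))
}
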