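events_tbl <- function(perch, land, leave, day = 1L, bird = 1L) {
  tibble::tibble(bird_id = bird, day = day, perch_id = perch,
                 t_land_s = land, t_leave_s = leave)
}

test_that("landing rate is a count ratio with missing (not zero) denominators", {
  ev <- events_tbl(c(rep(1L, 8), rep(2L, 2)), 1:10, 1:10 + 0.5)
  expect_equal(landing_rate(ev, perch_id = 1L), 0.8)
  expect_equal(landing_rate(ev, perch_id = 2L), 0.2)
  none <- ev[0, ]
  expect_true(is.na(landing_rate(none, perch_id = 1L)))
})

test_that("occupancy is a time ratio with lights-off clipped out", {
  ev <- events_tbl(c(1L, 2L), c(0, 100), c(30, 110))
  expect_equal(occupancy(ev, perch_id = 1L), 0.75)
  expect_equal(occupancy(ev, perch_id = 1L) + occupancy(ev, perch_id = 2L), 1)
  # bout straddling lights-off: 10 s before the boundary + 5 s after, only
  # the lights-on part counts
  sched <- day_schedule(0, 1000)
  strad <- events_tbl(c(1L, 2L), c(990, 0), c(1005, 10))
  expect_equal(occupancy(strad, perch_id = 1L, schedule = sched), 0.5)
  expect_true(is.na(occupancy(ev[0, ], perch_id = 1L)))
})

test_that("metrics are invariant to event-log row order", {
  ev <- events_tbl(c(1L, 2L, 1L, 2L), c(0, 40, 80, 120), c(30, 60, 110, 160))
  shuffled <- ev[c(3, 1, 4, 2), ]
  expect_equal(landing_rate(shuffled, perch_id = 1L),
               landing_rate(ev, perch_id = 1L))
  expect_equal(occupancy(shuffled, perch_id = 1L),
               occupancy(ev, perch_id = 1L))
})

test_that("singing track applies the 1 s margins and tiles the day", {
  # two syllables 0.5 s apart form one epoch; a 3 s gap splits epochs
  tr <- singing_track(onsets = c(10, 10.6, 20), offsets = c(10.5, 11, 20.4),
                      day_start = 0, day_end = 30)
  sing <- tr[tr$state == "singing", ]
  expect_equal(nrow(sing), 2)
  expect_equal(sing$start_s, c(9, 19))
  expect_equal(sing$end_s, c(12, 21.4))
  # tiles [0, 30] without overlap
  expect_equal(tr$start_s[-1], tr$end_s[-nrow(tr)])
  expect_equal(min(tr$start_s), 0)
  expect_equal(max(tr$end_s), 30)
  # a silent day is all non-singing
  quiet <- singing_track(numeric(0), numeric(0), 0, 30)
  expect_equal(quiet$state, "non_singing")
})

test_that("singing split apportions bouts by interval intersection", {
  # bird sings only while on perch 1; occupies both perches equally overall
  ev <- events_tbl(c(1L, 2L), c(0, 100), c(50, 150))
  track <- tibble::tibble(start_s = c(0, 50), end_s = c(50, 200),
                          state = c("singing", "non_singing"))
  sp <- split_by_singing(ev, track, perch_id = 1L)
  expect_equal(sp$singing, 1.0)
  expect_equal(sp$non_singing, 0.0)
  # no singing at all: singing occupancy missing, non-singing = overall
  all_quiet <- tibble::tibble(start_s = 0, end_s = 200, state = "non_singing")
  sp2 <- split_by_singing(ev, all_quiet, perch_id = 1L)
  expect_true(is.na(sp2$singing))
  expect_equal(sp2$non_singing, occupancy(ev, perch_id = 1L))
  # a non-tiling track is rejected
  broken <- tibble::tibble(start_s = c(0, 60), end_s = c(50, 200),
                           state = c("singing", "non_singing"))
  expect_error(split_by_singing(ev, broken, perch_id = 1L), "tile")
})

test_that("randomized singing labels equalize the state-conditioned occupancies", {
  set.seed(14)
  n <- 60
  land <- cumsum(runif(n, 5, 20))
  ev <- events_tbl(sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3)),
                   land, land + runif(n, 2, 10))
  day_end <- max(ev$t_leave_s) + 1
  # random 50/50 state track, independent of perch: expect singing ~ non-singing
  cuts <- sort(runif(40, 0, day_end))
  bounds <- c(0, cuts, day_end)
  track <- tibble::tibble(start_s = bounds[-length(bounds)], end_s = bounds[-1],
                          state = rep_len(c("singing", "non_singing"),
                                          length(bounds) - 1))
  sp <- split_by_singing(ev, track, perch_id = 1L)
  expect_lt(abs(sp$singing - sp$non_singing), 0.15)
})

test_that("daily pitch change is the mean day-to-day difference", {
  rend <- tibble::tibble(day = rep(1:3, each = 30),
                         pitch_hz = rep(c(600, 610, 620), each = 30))
  expect_equal(daily_pitch_change(rend), 10)
  flat <- tibble::tibble(day = rep(1:3, each = 30), pitch_hz = 600)
  expect_equal(daily_pitch_change(flat), 0)
  # days under the 20-rendition minimum do not qualify
  sparse <- tibble::tibble(day = c(rep(1, 30), rep(2, 5), rep(3, 30)),
                           pitch_hz = c(rep(600, 30), rep(900, 5), rep(620, 30)))
  expect_equal(daily_pitch_change(sparse), 10)  # (620-600)/2 days
  expect_true(is.na(daily_pitch_change(sparse[1:35, ])))
})

test_that("a configured daily drift is recovered from generated rendition logs", {
  ests <- sapply(1:20, function(s) {
    rend <- with(list(), {
      days <- 1:5
      do.call(rbind, lapply(days, function(d) {
        set.seed(derive_seed(s, "drift", d))
        tibble::tibble(day = d, pitch_hz = rnorm(400, 600 + 8 * d, 25))
      }))
    })
    daily_pitch_change(rend)
  })
  expect_lt(abs(mean(ests) - 8), 1.5)
})

test_that("one-sample t matches the closed-form statistic", {
  x <- c(0.8, 0.9, 0.85, 0.95)
  got <- one_sample_t(x, 0.5)
  t_hand <- (mean(x) - 0.5) / (sd(x) / sqrt(length(x)))
  expect_equal(got$t, t_hand)
  expect_equal(got$df, 3)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 3))
  # degenerate inputs
  flat <- one_sample_t(rep(0.5, 4), 0.5)
  expect_equal(flat$t, 0); expect_equal(flat$p, 1)
  up <- one_sample_t(rep(0.9, 4), 0.5)
  expect_true(is.infinite(up$t) && up$t > 0)
  expect_equal(up$p, 0)
  expect_true(up$degenerate)
})

test_that("two-way ANOVA equals the hand-computed balanced-design oracle", {
  # balanced 2x2, n = 3 per cell; closed-form sums of squares by hand
  d <- expand.grid(condition = c("A", "B"),
                   singing_state = c("singing", "non_singing"),
                   rep = 1:3)
  d$occupancy <- c(0.8, 0.3, 0.7, 0.4, 0.85, 0.35, 0.75, 0.45,
                   0.9, 0.25, 0.65, 0.5)
  grand <- mean(d$occupancy)
  cm <- tapply(d$occupancy, d$condition, mean)
  sm <- tapply(d$occupancy, d$singing_state, mean)
  cellm <- tapply(d$occupancy, list(d$condition, d$singing_state), mean)
  ss_c <- 6 * sum((cm - grand)^2)
  ss_s <- 6 * sum((sm - grand)^2)
  ss_cells <- 3 * sum((cellm - grand)^2)
  ss_int <- ss_cells - ss_c - ss_s
  ss_err <- sum((d$occupancy - cellm[cbind(as.character(d$condition),
                                           as.character(d$singing_state))])^2)
  an <- two_way_anova(d)
  expect_equal(an$condition$F, (ss_c / 1) / (ss_err / 8))
  expect_equal(an$singing_state$F, (ss_s / 1) / (ss_err / 8))
  expect_equal(an$interaction$F, (ss_int / 1) / (ss_err / 8))
  expect_equal(an$condition$df1, 1)
  expect_equal(an$condition$df2, 8)

  # identical cell means: all F = 0
  d0 <- d; d0$occupancy <- rep(c(0.5, 0.6, 0.7), each = 4)
  cell0 <- tapply(d0$occupancy, list(d0$condition, d0$singing_state), mean)
  expect_true(all(abs(cell0 - mean(d0$occupancy)) < 1e-12))
  an0 <- two_way_anova(d0)
  expect_equal(an0$condition$F, 0, tolerance = 1e-10)
  expect_equal(an0$interaction$F, 0, tolerance = 1e-10)

  # an empty design cell is an error naming the cell
  sub <- d[!(d$condition == "A" & d$singing_state == "singing"), ]
  expect_error(two_way_anova(sub), "empty design cell.*A.*singing")
})
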