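test_that("epoch scoring labels quiet epochs sleep and active epochs wake", {
  quiet <- make_record(rep(0, 120))
  expect_true(all(score_sleep_wake(quiet) == 1L))
  busy <- make_record(rep(500, 120))
  expect_true(all(score_sleep_wake(busy) == 0L))
  expect_error(score_sleep_wake(make_record(rep(0, 5))), "too-short")
})

test_that("night summaries match hand-counted sequences", {
  # 480-min interval, all asleep
  s <- rep(1L, 480)
  out <- summarize_night(s, c(1, 480))
  expect_equal(out$duration, 480)
  expect_equal(out$efficiency, 100)
  expect_equal(out$latency, 0)
  expect_equal(out$waso, 0)

  # 20 wake, 300 sleep, 20 wake, 140 sleep: hand-counted totals
  s2 <- c(rep(0L, 20), rep(1L, 300), rep(0L, 20), rep(1L, 140))
  out2 <- summarize_night(s2, c(1, 480))
  expect_equal(out2$duration, 440)
  expect_equal(out2$latency, 20)
  expect_equal(out2$waso, 20)
  expect_equal(out2$efficiency, 100 * 440 / 480, tolerance = 1e-10)

  # no sleep at all: zeros, latency = interval length, not an error
  out3 <- summarize_night(rep(0L, 60), c(1, 60))
  expect_equal(out3$duration, 0)
  expect_equal(out3$efficiency, 0)
  expect_equal(out3$latency, 60)
})

test_that("midpoint is circular across midnight", {
  # onset 23:00, offset 07:00 -> midpoint 03:00
  s <- rep(1L, 480)
  clock <- (23 + (seq_len(480) - 1) / 60) %% 24
  out <- summarize_night(s, c(1, 480), clock_hours = clock)
  expect_equal(out$onset, 23)
  # offset clock is the final sleep epoch's start, so allow one minute
  expect_equal(out$midpoint, 3, tolerance = 0.01)
})

test_that("component subscores follow the 0-3 bands monotonically", {
  expect_equal(component_subscore("efficiency", 95), 0L)
  expect_equal(component_subscore("efficiency", 80), 1L)
  expect_equal(component_subscore("efficiency", 70), 2L)
  expect_equal(component_subscore("efficiency", 60), 3L)
  expect_equal(component_subscore("latency", 10), 0L)
  expect_equal(component_subscore("latency", 61), 3L)
  expect_equal(component_subscore("duration", 200), 3L)
  expect_equal(component_subscore("duration", 430), 0L)
  expect_equal(component_subscore("waso", 15), 0L)
  expect_equal(component_subscore("waso", 65), 3L)
  expect_error(component_subscore("bogus", 1), "unknown component")
  # monotone: worse values never get lower subscores
  effs <- sapply(seq(100, 0, by = -5), component_subscore,
                 component = "efficiency")
  expect_true(all(diff(effs) >= 0))
  lats <- sapply(seq(0, 120, by = 5), component_subscore,
                 component = "latency")
  expect_true(all(diff(lats) >= 0))
})

mk_nights <- function(eff, lat, waso, dur, mid = 3,
                      day_type = rep(c("weekday", "weekend"), length.out = length(dur))) {
  data.frame(efficiency = eff, latency = lat, waso = waso, duration = dur,
             midpoint = mid, day_type = day_type)
}

test_that("weekly score spans 0-12 with the printed class boundaries", {
  best <- mk_nights(95, 5, 5, 480)
  lab <- sleep_qual_week(best)
  expect_equal(lab$score, 0)
  expect_equal(lab$class_id, 0L)

  worst <- mk_nights(50, 90, 90, 200)
  lab2 <- sleep_qual_week(worst)
  expect_equal(lab2$score, 12)
  expect_equal(lab2$class_id, 2L)

  expect_error(sleep_qual_week(mk_nights(95, 5, 5, 480)[0, ]), "night")
})

test_that("degrading any single component never lowers the weekly score", {
  base <- list(eff = 80, lat = 25, waso = 30, dur = 380)
  s0 <- sleep_qual_week(mk_nights(base$eff, base$lat, base$waso, base$dur))$score
  expect_gte(sleep_qual_week(mk_nights(70, base$lat, base$waso, base$dur))$score, s0)
  expect_gte(sleep_qual_week(mk_nights(base$eff, 70, base$waso, base$dur))$score, s0)
  expect_gte(sleep_qual_week(mk_nights(base$eff, base$lat, 70, base$dur))$score, s0)
  expect_gte(sleep_qual_week(mk_nights(base$eff, base$lat, base$waso, 250))$score, s0)
})

test_that("consistency score combines weighted components and classes", {
  # identical nights, no weekend shift: all components 0
  same <- mk_nights(90, 10, 10, c(440, 440, 440, 440), mid = 3,
                    day_type = c("weekday", "weekday", "weekend", "weekend"))
  lab <- sleep_cons(same)
  expect_equal(lab$score, 0)
  expect_equal(lab$class_id, 0L)

  expect_error(sleep_cons(same[1, , drop = FALSE]), "two nights")

  # no weekend nights: WeekendDiff 0 with a warning
  wd_only <- mk_nights(90, 10, 10, c(400, 480), mid = c(2, 4),
                       day_type = c("weekday", "weekday"))
  expect_warning(lab2 <- sleep_cons(wd_only), "Weekend")
  expect_equal(unname(lab2$components["weekend_diff"]), 0)
})

test_that("consistency components carry the stated weights", {
  # construct nights whose components are known: durations with SD 100,
  # midpoints identical within day type, separated by 100 minutes
  dur <- c(340, 540, 340, 540, 340, 540)  # sample SD
  sd_dur <- sd(dur)
  nights <- mk_nights(90, 10, 10, dur,
                      mid = c(3, 3, 3, 3, 3 + 100 / 60, 3 + 100 / 60),
                      day_type = c(rep("weekday", 4), rep("weekend", 2)))
  lab <- sleep_cons(nights)
  expect_equal(unname(lab$components["weekend_diff"]), 100, tolerance = 1e-6)
  expect_equal(unname(lab$components["sleep_var"]), sd_dur)
  expect_equal(lab$score,
               0.4 * sd_dur + 0.3 * 100 +
                 0.3 * unname(lab$components["midpoint_var"]),
               tolerance = 1e-8)
})

test_that("consistency score is invariant to night order within day type", {
  dur <- c(300, 420, 500, 380, 460, 350, 410)
  mid <- c(2.5, 3.2, 2.8, 3.6, 2.9, 4.1, 4.5)
  dt <- c(rep("weekday", 5), rep("weekend", 2))
  n1 <- mk_nights(90, 10, 10, dur, mid, dt)
  perm <- c(3, 1, 5, 2, 4, 7, 6)   # permutes within each day type
  n2 <- n1[perm, ]
  expect_equal(sleep_cons(n1)$score, sleep_cons(n2)$score)
})

test_that("doubling dispersion at least doubles the dispersion terms", {
  dur <- c(400, 440, 380, 460, 420, 430, 390)
  mid <- c(3, 3.4, 2.7, 3.8, 3.1, 3.3, 2.9)
  dt <- c(rep("weekday", 5), rep("weekend", 2))
  n1 <- mk_nights(90, 10, 10, dur, mid, dt)
  n2 <- mk_nights(90, 10, 10, mean(dur) + 2 * (dur - mean(dur)),
                  3.15 + 2 * (mid - 3.15), dt)
  c1 <- sleep_cons(n1)$components
  c2 <- sleep_cons(n2)$components
  expect_gte(c2[["sleep_var"]], 2 * c1[["sleep_var"]] - 1e-8)
  expect_gte(c2[["midpoint_var"]], 2 * c1[["midpoint_var"]] - 1e-2)
})

test_that("synthetic nights are recovered within tolerance at low noise", {
  hits_dur <- hits_eff <- 0; total <- 0
  for (s in 1:6) {
    out <- generate_participant(low_noise_profile(), n_days = 7, seed = s)
    nights <- score_record(out$record)
    n <- min(nrow(nights), nrow(out$truth))
    total <- total + n
    hits_dur <- hits_dur +
      sum(abs(nights$duration[1:n] - out$truth$duration[1:n]) <= 10)
    hits_eff <- hits_eff +
      sum(abs(nights$efficiency[1:n] - out$truth$efficiency[1:n]) <= 5)
  }
  expect_gte(hits_dur / total, 0.9)
  expect_gte(hits_eff / total, 0.9)
})

test_that("onset and offset are recovered within ten minutes", {
  out <- generate_participant(low_noise_profile(), n_days = 7, seed = 21)
  nights <- score_record(out$record)
  n <- min(nrow(nights), nrow(out$truth))
  donset <- abs(nights$onset[1:n] - out$truth$onset[1:n])
  donset <- pmin(donset, 24 - donset) * 60
  expect_true(all(donset <= 10))
})
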