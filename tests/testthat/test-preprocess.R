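test_that("edge trimming drops only leading/trailing off-wrist runs", {
  counts <- c(rep(NA, 10), rep(5, 100), rep(NA, 5))
  off <- c(rep(1L, 10), rep(0L, 100), rep(1L, 5))
  rec <- make_record(counts, off)
  tr <- trim_offwrist_edges(rec)
  expect_length(tr$activity, 100)

  clean <- make_record(rep(3, 80))
  expect_equal(trim_offwrist_edges(clean)$activity, clean$activity)

  # interior off-wrist retained as missing counts
  counts2 <- c(rep(2, 30), rep(NA, 10), rep(4, 30))
  off2 <- c(rep(0L, 30), rep(1L, 10), rep(0L, 30))
  tr2 <- trim_offwrist_edges(make_record(counts2, off2))
  expect_length(tr2$activity, 70)
  expect_true(all(is.na(tr2$activity[31:40])))

  expect_error(trim_offwrist_edges(make_record(rep(NA, 5), rep(1L, 5))),
               "off-wrist")
})

test_that("forward fill propagates the most recent valid count", {
  rec <- make_record(c(3, NA, NA, 7))
  expect_equal(forward_fill(rec)$activity, c(3, 3, 3, 7))
  full <- make_record(c(1, 2, 3))
  expect_equal(forward_fill(full)$activity, c(1, 2, 3))
  expect_error(forward_fill(make_record(c(NA, 5))), "state error")
})

test_that("hourly downsampling equals the arithmetic mean per hour", {
  expect_equal(downsample_hourly(make_record(rep(10, 60)))$values, 10)
  expect_equal(downsample_hourly(make_record(c(rep(0, 60), rep(6, 60))))$values,
               c(0, 6))
  expect_equal(downsample_hourly(make_record(1:60))$values, 30.5)
  # trailing partial hour dropped
  expect_equal(downsample_hourly(make_record(c(rep(2, 60), rep(9, 30))))$values, 2)
  expect_error(downsample_hourly(make_record(rep(1, 59))), "too-short")
})

test_that("window counts follow floor((L - 24) / 12) + 1", {
  mk <- function(L) structure(list(participant_id = "T", values = seq_len(L),
                                   start_time = t_base),
                              class = "hourly_series")
  expect_equal(nrow(make_windows(mk(168))$windows), 13)
  expect_equal(nrow(make_windows(mk(24))$windows), 1)
  expect_equal(nrow(make_windows(mk(35))$windows), 1)
  expect_equal(nrow(make_windows(mk(36))$windows), 2)
  expect_error(make_windows(mk(23)), "too-short")
  # consecutive starts differ by the step
  expect_equal(diff(make_windows(mk(168))$start_hours), rep(12L, 12))
  # every hour covered when (L - 24) %% 12 == 0
  ws <- make_windows(mk(96))
  covered <- sort(unique(as.vector(
    outer(ws$start_hours, seq_len(24), `+`))))
  expect_equal(covered, 1:96)
})

test_that("min-max normalisation maps extremes to 0/1 and constants to 0", {
  mk_ws <- function(m) structure(list(windows = m, start_hours = 0L,
                                      participant_id = "T"),
                                 class = "window_set")
  w <- mk_ws(matrix(c(0, 5, 10, 2, 2, 2), 1))
  out <- minmax_normalize(w, "per_record")
  expect_equal(range(out$windows), c(0, 1))
  expect_equal(out$windows[1, 1:3], c(0, 0.5, 1))

  const <- minmax_normalize(mk_ws(matrix(7, 2, 24)), "per_record")
  expect_true(all(const$windows == 0))

  pw <- minmax_normalize(mk_ws(matrix(c(1:24, 24:1), 2, byrow = TRUE)),
                         "per_window")
  expect_equal(range(pw$windows[1, ]), c(0, 1))
  expect_equal(range(pw$windows[2, ]), c(0, 1))
})

test_that("preprocessing agrees with brute-force oracles on random records", {
  withr::with_seed(42, {
    for (i in 1:25) {
      n_hours <- sample(24:72, 1)
      x <- rpois(n_hours * 60 + sample(0:59, 1), lambda = 40)
      x[sample(seq_along(x)[-1], length(x) %/% 10)] <- NA
      rec <- make_record(x)
      filled <- forward_fill(rec)
      expect_equal(filled$activity, ff_oracle(x))
      hs <- downsample_hourly(filled)
      expect_equal(hs$values, hourly_oracle(filled$activity))
      ws <- minmax_normalize(make_windows(hs), "per_record")
      expect_equal(nrow(ws$windows), (n_hours - 24) %/% 12 + 1)
      raw <- make_windows(hs)$windows
      expect_equal(as.numeric(ws$windows), minmax_oracle(as.numeric(raw)))
    }
  })
})

test_that("the chain is idempotent from the hourly stage onward", {
  out <- generate_participant(sleep_profile(), n_days = 3, seed = 2)
  ws1 <- preprocess_record(out$record)
  ws2 <- minmax_normalize(ws1, "per_record")
  expect_equal(ws1$windows, ws2$windows)
})
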