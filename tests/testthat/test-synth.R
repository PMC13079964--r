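test_that("generated records have the expected epoch grid and determinism", {
  out <- generate_participant(sleep_profile(), n_days = 7, seed = 1)
  expect_s3_class(out$record, "actigraphy_record")
  expect_length(out$record$activity, 7 * 1440)
  expect_equal(nrow(out$truth), 7)

  out2 <- generate_participant(sleep_profile(), n_days = 7, seed = 42)
  out3 <- generate_participant(sleep_profile(), n_days = 7, seed = 42)
  expect_identical(out2$record$activity, out3$record$activity)
  expect_identical(out2$truth, out3$truth)
  expect_false(identical(out$record$activity, out2$record$activity))
})

test_that("degenerate noise gives exactly zero nocturnal counts", {
  prof <- sleep_profile(night_activity_mean = 0, count_dispersion = 0,
                        waso_mean = 0, latency_mean = 0,
                        efficiency_target = 100)
  out <- generate_participant(prof, n_days = 2, seed = 5)
  tr <- out$truth
  # locate asleep epochs from the drawn onset/duration (no WASO, no latency)
  for (d in seq_len(nrow(tr)) - 1) {
    onset_min <- d * 1440 + round(((tr$onset[d + 1] - 12) %% 24) * 60)
    idx <- onset_min + seq_len(tr$duration[d + 1]) - 1
    idx <- idx[idx < length(out$record$activity)]
    expect_true(all(out$record$activity[idx + 1] == 0))
  }
})

test_that("profile invariants are enforced", {
  expect_error(sleep_profile(efficiency_target = 0), "efficiency_target")
  expect_error(sleep_profile(efficiency_target = 101), "efficiency_target")
  expect_error(sleep_profile(waso_mean = -1), "waso_mean")
  expect_error(sleep_profile(day_activity_mean = 1, night_activity_mean = 2),
               "night_activity_mean")
  expect_error(generate_participant(sleep_profile(), n_days = 0), "n_days")
})

test_that("default cohorts have the study shapes with matching classes", {
  co <- generate_cohort(metric = "SleepQualWeek", seed = 3)
  expect_length(co$records, 28)
  expect_equal(as.vector(table(co$meta$requested_class)), c(10, 10, 8))
  # ground-truth classes equal requested classes for the weekly metric
  expect_equal(as.character(co$meta$sqw_class), co$meta$requested_class)

  co2 <- generate_cohort(metric = "SleepCons", seed = 3)
  expect_length(co2$records, 40)
  expect_equal(as.vector(table(co2$meta$requested_class)), rep(10, 4))
  # cohort-level class realizability
  expect_gte(mean(co2$meta$requested_class == as.character(co2$meta$cons_class)),
             0.9)

  one <- generate_cohort(list(a = list(profile = sleep_profile(), n = 1)),
                         n_days = 3, seed = 1)
  expect_length(one$records, 1)
  expect_error(generate_cohort(list(), seed = 1), "class")
})

test_that("cohorts are reproducible bitwise for a fixed seed", {
  a <- generate_cohort(metric = "SleepQualWeek", seed = 11, n_days = 2)
  b <- generate_cohort(metric = "SleepQualWeek", seed = 11, n_days = 2)
  for (pid in names(a$records))
    expect_identical(a$records[[pid]]$activity, b$records[[pid]]$activity)
})

test_that("off-wrist injection flags exactly the requested half-open segments", {
  rec <- make_record(rep(5, 200))
  expect_identical(inject_offwrist(rec, list()), rec)

  r2 <- inject_offwrist(rec, list(c(1, 61)))
  expect_equal(sum(r2$offwrist), 60)
  expect_true(all(is.na(r2$activity[1:60])))
  expect_equal(r2$activity[61:200], rec$activity[61:200])

  expect_error(inject_offwrist(rec, list(c(150, 250))), "segment")
  expect_error(inject_offwrist(rec, list(c(1, 10), c(5, 12))), "overlap")
})
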