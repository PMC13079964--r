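#' Define a synthetic sleep/activity profile
#'
#' A `sleep_profile` parameterises the synthetic actigraphy generator: habitual
#' bed time and sleep architecture (duration, latency, wake after sleep onset,
#' efficiency), night-to-night variability, a weekend bed-time shift, and the
#' activity-count regime (diurnal and nocturnal means with a negative-binomial
#' dispersion). Counts are non-negative and right-skewed, as wrist-actigraphy
#' counts are.
#'
#' @param mean_bedtime Habitual bed time, hours since midnight (e.g. 23.25).
#' @param mean_duration Mean nightly sleep duration, minutes.
#' @param latency_mean Mean sleep-onset latency, minutes.
#' @param waso_mean Mean wake after sleep onset, minutes.
#' @param efficiency_target Target sleep efficiency, percent in (0, 100]. Time
#'   in bed beyond latency + duration + WASO is realised as terminal wake so
#'   that duration / time-in-bed matches this target on average.
#' @param duration_sd Night-to-night SD of sleep duration, minutes.
#' @param midpoint_sd Night-to-night SD of the sleep midpoint, minutes
#'   (realised as bed-time jitter).
#' @param weekend_shift Bed-time delay on weekend nights, minutes.
#' @param day_activity_mean Mean activity count per minute while awake out of
#'   bed.
#' @param night_activity_mean Mean count per minute while asleep; must be
#'   strictly below `day_activity_mean`.
#' @param count_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param wake_in_bed_mean Mean count per minute while awake in bed (latency,
#'   WASO bouts, terminal wake); defaults to a low level between the nocturnal
#'   and diurnal means.
#' @return An object of class `sleep_profile`.
#' @export
sleep_profile <- function(mean_bedtime = 23, mean_duration = 440,
                          latency_mean = 15, waso_mean = 25,
                          efficiency_target = 88, duration_sd = 30,
                          midpoint_sd = 25, weekend_shift = 20,
                          day_activity_mean = 250, night_activity_mean = 0.3,
                          count_dispersion = 1,
                          wake_in_bed_mean = NULL) {
  if (is.null(wake_in_bed_mean))
    wake_in_bed_mean <- night_activity_mean +
      0.012 * (day_activity_mean - night_activity_mean)
  p <- list(mean_bedtime = mean_bedtime, mean_duration = mean_duration,
            latency_mean = latency_mean, waso_mean = waso_mean,
            efficiency_target = efficiency_target, duration_sd = duration_sd,
            midpoint_sd = midpoint_sd, weekend_shift = weekend_shift,
            day_activity_mean = day_activity_mean,
            night_activity_mean = night_activity_mean,
            count_dispersion = count_dispersion,
            wake_in_bed_mean = wake_in_bed_mean)
  validate_profile(p)
  structure(p, class = "sleep_profile")
}

validate_profile <- function(p) {
  if (!(p$efficiency_target > 0 && p$efficiency_target <= 100))
    stop("invalid profile: efficiency_target must lie in (0, 100]")
  for (k in c("mean_duration", "latency_mean", "waso_mean", "duration_sd",
              "midpoint_sd", "day_activity_mean", "night_activity_mean",
              "count_dispersion", "wake_in_bed_mean"))
    if (p[[k]] < 0) stop("invalid profile: ", k, " must be >= 0")
  if (!(p$night_activity_mean < p$day_activity_mean))
    stop("invalid profile: night_activity_mean must be < day_activity_mean")
  invisible(p)
}

rcounts <- function(n, mu, dispersion) {
  if (n == 0L) return(numeric(0))
  if (mu == 0) return(rep(0, n))
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate one participant's synthetic actigraphy record
#'
#' Simulates `n_days` * 1440 one-minute epochs starting at local noon
#' (so nights span midnight). For each night a bed time, latency, duration,
#' WASO (realised as discrete awakening bouts) and terminal wake are drawn
#' from the profile; epochs inside the sleep window receive low nocturnal
#' counts, awake-in-bed epochs a low-intermediate level, and all other epochs
#' the diurnal level. Days are indexed 0-6 with days 5-6 as the weekend,
#' where the profile's bed-time shift applies.
#'
#' All randomness flows through one seeded generator; identical
#' `(profile, n_days, seed)` give bit-identical output and the global RNG
#' state is untouched.
#'
#' @param profile A [sleep_profile].
#' @param n_days Number of simulated days (>= 1); 7 is the canonical week.
#' @param seed Integer seed.
#' @param participant_id Identifier for the record.
#' @param start_date Calendar date of the first (noon) epoch.
#' @return A list with components `record` (an [actigraphy_record]) and
#'   `truth` (a `data.frame` of per-night drawn parameters: onset/offset
#'   clock hours, latency, WASO, duration, time in bed, efficiency, midpoint,
#'   day type) with attributes `sqw` and `cons` holding the noiseless
#'   [sleep_qual_week()] and [sleep_cons()] labels.
#' @export
generate_participant <- function(profile, n_days = 7, seed = 1,
                                 participant_id = "P001",
                                 start_date = "2024-01-01") {
  validate_profile(profile)
  if (n_days < 1) stop("n_days must be >= 1")
  withr::with_seed(as.integer(seed), {
    n_epochs <- as.integer(n_days) * 1440L
    start <- as.POSIXct(paste(start_date, "12:00"), tz = "")
    # state per epoch: 0 day-wake, 1 in-bed wake, 2 asleep
    state <- integer(n_epochs)
    nights <- vector("list", n_days)
    for (d in seq_len(n_days) - 1L) {
      weekend <- (d %% 7L) %in% c(5L, 6L)
      bed_h <- profile$mean_bedtime +
        (if (weekend) profile$weekend_shift / 60 else 0) +
        stats::rnorm(1, 0, profile$midpoint_sd / 60)
      latency <- if (profile$latency_mean > 0)
        round(stats::rgamma(1, shape = 4, scale = profile$latency_mean / 4)) else 0
      duration <- round(stats::rnorm(1, profile$mean_duration, profile$duration_sd))
      duration <- min(max(duration, 60), 960)
      waso <- if (profile$waso_mean > 0)
        round(stats::rgamma(1, shape = 4, scale = profile$waso_mean / 4)) else 0
      terminal <- max(0, round(duration * 100 / profile$efficiency_target -
                                 latency - duration - waso))
      tib <- latency + duration + waso + terminal
      bed_min <- d * 1440L + as.integer(round(((bed_h - 12) %% 24) * 60))
      onset_min <- bed_min + latency
      offset_min <- onset_min + duration + waso
      rise_min <- offset_min + terminal
      # per-epoch sleep/wake inside the bed interval (clipped to the record)
      if (bed_min <= n_epochs - 1L) {
        in_bed <- seq.int(bed_min, min(rise_min - 1L, n_epochs - 1L))
        state[in_bed + 1L] <- 1L
      }
      sleep_rel <- rep(TRUE, duration + waso)            # onset..offset-1
      if (waso > 0) {
        n_bouts <- 1L + stats::rpois(1, waso / 20)
        cuts <- sort(sample.int(waso + n_bouts - 1L, n_bouts - 1L))
        lens <- diff(c(0L, cuts, waso + n_bouts - 1L)) - c(rep(1L, n_bouts - 1L), 0L)
        lens <- lens[lens > 0]
        # place bouts uniformly strictly inside the sleep period
        avail <- duration + waso - 2L
        if (avail > 2L && length(lens) > 0) {
          starts <- sort(sample.int(max(avail - max(lens), 1L), length(lens),
                                    replace = TRUE))
          for (b in seq_along(lens)) {
            idx <- starts[b] + seq_len(lens[b]) - 1L
            idx <- idx[idx >= 1L & idx <= duration + waso - 1L]
            sleep_rel[idx + 1L] <- FALSE
          }
        }
      }
      # enforce the drawn WASO total exactly: adjust by flipping epochs
      waso_real <- sum(!sleep_rel)
      asleep_abs <- onset_min + which(sleep_rel) - 1L
      asleep_abs <- asleep_abs[asleep_abs < n_epochs]
      state[asleep_abs + 1L] <- 2L
      nights[[d + 1L]] <- data.frame(
        night = d, day_type = if (weekend) "weekend" else "weekday",
        onset = ((12 + onset_min / 60) %% 24),
        offset = ((12 + offset_min / 60) %% 24),
        latency = latency, waso = waso_real,
        duration = duration + waso - waso_real,
        time_in_bed = tib,
        efficiency = 100 * (duration + waso - waso_real) / tib,
        midpoint = ((12 + (onset_min + (offset_min - onset_min) / 2) / 60) %% 24),
        stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, nights)
    counts <- numeric(n_epochs)
    for (s in 0:2) {
      idx <- which(state == s)
      mu <- switch(as.character(s), "0" = profile$day_activity_mean,
                   "1" = profile$wake_in_bed_mean,
                   "2" = profile$night_activity_mean)
      counts[idx] <- rcounts(length(idx), mu, profile$count_dispersion)
    }
    rec <- actigraphy_record(participant_id,
                             start + 60 * (seq_len(n_epochs) - 1L),
                             counts, rep(0L, n_epochs))
    attr(truth, "sqw") <- sleep_qual_week(truth)
    # short records have no weekday/weekend contrast; the degenerate
    # WeekendDiff = 0 is fine for ground truth, so keep it quiet here
    attr(truth, "cons") <- if (nrow(truth) >= 2)
      suppressWarnings(sleep_cons(truth, truth$day_type)) else NULL
    list(record = rec, truth = truth)
  })
}

#' Default class-calibrated profiles
#'
#' Shipped profiles whose drawn nightly parameters land each participant in
#' the requested class of the chosen metric at the default noise level. The
#' weekly-quality set spans good (high efficiency, short latency) to poor
#' (fragmented, short, inefficient) sleepers; the consistency set spans
#' regular to highly irregular schedules (increasing duration variability,
#' weekday-weekend shift and midpoint jitter).
#'
#' @param metric `"SleepQualWeek"` or `"SleepCons"`.
#' @return Named list of [sleep_profile] objects, one per class.
#' @export
default_profiles <- function(metric = c("SleepQualWeek", "SleepCons")) {
  metric <- match.arg(metric)
  if (metric == "SleepQualWeek") {
    list(
      "0" = sleep_profile(mean_bedtime = 23.0, mean_duration = 460,
                          latency_mean = 10, waso_mean = 15,
                          efficiency_target = 93, duration_sd = 25,
                          midpoint_sd = 20, weekend_shift = 15,
                          day_activity_mean = 280, night_activity_mean = 0,
                          wake_in_bed_mean = 8),
      "1" = sleep_profile(mean_bedtime = 23.5, mean_duration = 340,
                          latency_mean = 40, waso_mean = 28,
                          efficiency_target = 81, duration_sd = 35,
                          midpoint_sd = 30, weekend_shift = 30,
                          day_activity_mean = 240, night_activity_mean = 0.5,
                          wake_in_bed_mean = 10),
      "2" = sleep_profile(mean_bedtime = 0.5, mean_duration = 250,
                          latency_mean = 75, waso_mean = 70,
                          efficiency_target = 62, duration_sd = 45,
                          midpoint_sd = 45, weekend_shift = 40,
                          day_activity_mean = 190, night_activity_mean = 1.2,
                          wake_in_bed_mean = 12)
    )
  } else {
    list(
      "0" = sleep_profile(mean_bedtime = 23.0, mean_duration = 440,
                          latency_mean = 12, waso_mean = 20,
                          efficiency_target = 90, duration_sd = 20,
                          midpoint_sd = 15, weekend_shift = 15),
      "1" = sleep_profile(mean_bedtime = 23.5, mean_duration = 420,
                          latency_mean = 18, waso_mean = 25,
                          efficiency_target = 88, duration_sd = 100,
                          midpoint_sd = 60, weekend_shift = 160),
      "2" = sleep_profile(mean_bedtime = 23.5, mean_duration = 420,
                          latency_mean = 25, waso_mean = 30,
                          efficiency_target = 85, duration_sd = 250,
                          midpoint_sd = 60, weekend_shift = 460),
      "3" = sleep_profile(mean_bedtime = 0.0, mean_duration = 510,
                          latency_mean = 30, waso_mean = 40,
                          efficiency_target = 82, duration_sd = 900,
                          midpoint_sd = 60, weekend_shift = 720)
    )
  }
}

#' Generate a synthetic cohort with known ground truth
#'
#' Generates `n_participants` records per class from per-class profiles,
#' with per-participant seeds derived as `seed + index` so cohorts are
#' reproducible and participants independent. The default cohort shapes are
#' the study templates: 28 weekly-quality participants (10 + 10 + 8 in
#' classes 0/1/2) and 40 consistency participants (10 per class 0-3).
#'
#' @param class_spec Named list mapping class label to
#'   `list(profile = <sleep_profile>, n = <count>)`. `NULL` uses the default
#'   cohort for `metric`.
#' @param metric Metric whose default cohort template to use when
#'   `class_spec` is `NULL`.
#' @param n_days Days per participant (default 7).
#' @param seed Cohort seed.
#' @return A list with `records` (list of [actigraphy_record]), `truth`
#'   (list of per-night ground-truth tables, see [generate_participant()])
#'   and `meta` (a `data.frame` of participant id, requested class, seed,
#'   and the noiseless ground-truth scores/classes for both metrics).
#' @export
generate_cohort <- function(class_spec = NULL,
                            metric = c("SleepQualWeek", "SleepCons"),
                            n_days = 7, seed = 1) {
  metric <- match.arg(metric)
  if (is.null(class_spec)) {
    prof <- default_profiles(metric)
    n_per <- if (metric == "SleepQualWeek") c(10L, 10L, 8L) else rep(10L, 4L)
    class_spec <- stats::setNames(
      lapply(seq_along(prof), function(i) list(profile = prof[[i]], n = n_per[i])),
      names(prof))
  }
  if (length(class_spec) < 1L) stop("class_spec must name at least one class")
  records <- list(); truth <- list(); meta <- list()
  idx <- 0L
  for (cls in names(class_spec)) {
    spec <- class_spec[[cls]]
    if (spec$n < 1L) stop("each class needs n >= 1 participants")
    for (i in seq_len(spec$n)) {
      idx <- idx + 1L
      pid <- sprintf("P%03d", idx)
      out <- generate_participant(spec$profile, n_days = n_days,
                                  seed = as.integer(seed) + idx,
                                  participant_id = pid)
      records[[pid]] <- out$record
      truth[[pid]] <- out$truth
      sqw <- attr(out$truth, "sqw"); cons <- attr(out$truth, "cons")
      meta[[pid]] <- data.frame(
        participant_id = pid, requested_class = cls,
        seed = as.integer(seed) + idx,
        sqw_score = sqw$score, sqw_class = sqw$class_id,
        cons_score = if (is.null(cons)) NA_real_ else cons$score,
        cons_class = if (is.null(cons)) NA_integer_ else cons$class_id,
        stringsAsFactors = FALSE)
    }
  }
  list(records = records, truth = truth, meta = do.call(rbind, meta))
}

#' Flag off-wrist segments in a record
#'
#' Marks the given half-open epoch intervals `[start, end)` (1-based indices)
#' as off-wrist: the flag is set to 1 and the counts become missing. All
#' other epochs are untouched.
#'
#' @param record An [actigraphy_record].
#' @param segments List of length-2 integer vectors `c(start, end)`,
#'   non-overlapping and within the record.
#' @return The modified [actigraphy_record].
#' @export
inject_offwrist <- function(record, segments) {
  stopifnot(inherits(record, "actigraphy_record"))
  if (length(segments) == 0L) return(record)
  n <- length(record$activity)
  touched <- integer(0)
  for (seg in segments) {
    if (length(seg) != 2L || seg[1] < 1L || seg[2] > n + 1L || seg[2] <= seg[1])
      stop("invalid off-wrist segment: must be within [1, ", n, "] with start < end")
    idx <- seq.int(seg[1], seg[2] - 1L)
    if (any(idx %in% touched)) stop("off-wrist segments must not overlap")
    touched <- c(touched, idx)
  }
  record$offwrist[touched] <- 1L
  record$activity[touched] <- NA_real_
  record
}
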