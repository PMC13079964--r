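# circular helpers on the 24-h clock ------------------------------------------

hours_to_angle <- function(h) h / 24 * 2 * pi

circ_mean_hours <- function(h) {
  a <- hours_to_angle(h)
  m <- atan2(mean(sin(a)), mean(cos(a)))
  (m / (2 * pi) * 24) %% 24
}

# circular standard deviation, expressed in minutes on the 24-h wheel
circ_sd_minutes <- function(h) {
  a <- hours_to_angle(h)
  R <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  R <- min(max(R, 1e-12), 1)
  sqrt(-2 * log(R)) / (2 * pi) * 1440
}

# absolute circular difference between two clock times, in minutes (<= 720)
circ_diff_minutes <- function(h1, h2) {
  d <- abs(h1 - h2) %% 24
  min(d, 24 - d) * 60
}

#' Score each epoch sleep or wake
#'
#' Cole-Kripke style scoring for one-minute epochs: a weighted moving sum of
#' activity counts over a 7-epoch window (four before, the current, two
#' after) is compared to a threshold; below threshold scores sleep. Optional
#' Webster rescoring reclassifies short sleep runs following sustained wake.
#'
#' @param record A gap-free [actigraphy_record].
#' @param config Configuration list; uses the `scoring` block (weights,
#'   threshold, `webster_rescore`).
#' @return Integer vector, 1 = sleep, 0 = wake, one element per epoch.
#' @export
score_sleep_wake <- function(record, config = sleepmos_config()) {
  stopifnot(inherits(record, "actigraphy_record"))
  sc <- config$scoring
  x <- record$activity
  if (anyNA(x)) stop("state error: record has missing counts; preprocess first")
  w <- sc$weights
  k <- length(w)                       # 7: offsets -4..+2
  if (length(x) < k)
    stop("too-short error: record shorter than the ", k, "-epoch scoring window")
  xp <- c(rep(x[1], 4L), x, rep(x[length(x)], 2L))
  d <- numeric(length(x))
  for (j in seq_len(k)) d <- d + w[j] * xp[seq_along(x) + (j - 1L)]
  s <- as.integer(d < sc$threshold)
  if (isTRUE(sc$webster_rescore)) s <- webster_rescore(s)
  s
}

# Webster rules a-c: after >= 4/10/15 min scored wake, the next 1/3/4 min of
# sleep are rescored wake
webster_rescore <- function(s) {
  n <- length(s)
  run_wake <- 0L
  i <- 1L
  while (i <= n) {
    if (s[i] == 0L) {
      run_wake <- run_wake + 1L
    } else {
      resc <- if (run_wake >= 15L) 4L else if (run_wake >= 10L) 3L else
        if (run_wake >= 4L) 1L else 0L
      j <- 0L
      while (j < resc && i + j <= n && s[i + j] == 1L) {
        s[i + j] <- 0L
        j <- j + 1L
      }
      i <- i + max(j - 1L, 0L)
      run_wake <- 0L
    }
    i <- i + 1L
  }
  s
}

#' Detect nightly rest intervals from activity quiescence
#'
#' For each night the record covers, searches the window from evening
#' (default 18:00) to the following noon for the longest sustained run of
#' quiescent epochs, where quiescence means the centred moving-average count
#' falls below a data-adaptive threshold (a fraction of the record's
#' high-activity level). The longest run is taken as the in-bed (rest)
#' interval for that night. Nights with no run of at least `min_minutes`
#' are skipped.
#'
#' @param record A gap-free [actigraphy_record].
#' @param config Configuration list (`scoring` block).
#' @param min_minutes Minimum credible rest-interval length.
#' @return `data.frame` with one row per detected night: `night` (0-based),
#'   `start`, `end` (1-based epoch indices, inclusive), `day_type`.
#' @export
detect_rest_intervals <- function(record, config = sleepmos_config(),
                                  min_minutes = 120L) {
  sc <- config$scoring
  x <- record$activity
  if (anyNA(x)) stop("state error: record has missing counts; preprocess first")
  n <- length(x)
  sm <- as.numeric(stats::filter(x, rep(1 / sc$rest_smooth_epochs,
                                        sc$rest_smooth_epochs), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  day_level <- mean(x[x > stats::median(x)])
  if (!is.finite(day_level)) day_level <- max(x)
  thr <- max(sc$rest_threshold_min, sc$rest_threshold_frac * day_level)
  quiet <- sm < thr
  t0 <- record$timestamp[1]
  date0 <- as.Date(format(t0, "%Y-%m-%d"))
  # minutes from local midnight of the record's first day
  min0 <- as.integer(format(t0, "%H")) * 60L + as.integer(format(t0, "%M"))
  out <- list()
  night <- 0L
  for (d in 0:(ceiling((min0 + n) / 1440) + 1L)) {
    a <- d * 1440L + round(sc$rest_search_start_hour * 60) - min0 + 1L
    b <- (d + 1L) * 1440L + round(sc$rest_search_end_hour * 60) - min0
    a <- max(a, 1L); b <- min(b, n)
    if (b - a + 1L < min_minutes) next
    q <- quiet[a:b]
    r <- rle(q)
    if (!any(r$values & r$lengths >= min_minutes)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    best <- which(r$values)[which.max(r$lengths[r$values])]
    s_idx <- a + starts[best] - 1L
    e_idx <- a + ends[best] - 1L
    if (length(out) > 0 && s_idx <= out[[length(out)]]$end) next
    wd <- as.integer(format(date0 + d, "%u"))   # 1 = Monday ... 7 = Sunday
    out[[length(out) + 1L]] <- data.frame(
      night = night, start = s_idx, end = e_idx,
      day_type = if (wd %in% c(6L, 7L)) "weekend" else "weekday",
      stringsAsFactors = FALSE)
    night <- night + 1L
  }
  if (length(out) == 0L)
    return(data.frame(night = integer(0), start = integer(0),
                      end = integer(0), day_type = character(0)))
  do.call(rbind, out)
}

#' Summarise one night from an epoch sleep/wake sequence
#'
#' Within the rest (in-bed) interval: latency is the minutes from interval
#' start to the first persistent sleep run; sleep onset is the start of that
#' run and offset the last sleep epoch; WASO is the wake minutes strictly
#' between onset and offset; duration is the total sleep minutes in the
#' interval; efficiency is 100 * duration / time-in-bed; the midpoint is the
#' clock time halfway between onset and offset (circular across midnight).
#' An interval with no persistent sleep yields duration 0, efficiency 0 and
#' latency equal to the interval length (not an error).
#'
#' @param sleep_wake Integer vector (1 = sleep, 0 = wake) for the record.
#' @param rest_interval Length-2 vector `c(start, end)` of 1-based epoch
#'   indices, inclusive; must span at most 24 h.
#' @param clock_hours Optional numeric vector of clock hours (0-24) per
#'   epoch, used for onset/offset/midpoint; if `NULL` these are `NA`.
#' @param persistent Epochs of consecutive sleep defining persistent sleep
#'   onset.
#' @return One-row `data.frame`: `onset`, `offset`, `midpoint` (clock
#'   hours), `latency`, `waso`, `duration`, `time_in_bed` (minutes),
#'   `efficiency` (percent).
#' @export
summarize_night <- function(sleep_wake, rest_interval, clock_hours = NULL,
                            persistent = 5L) {
  a <- rest_interval[1]; b <- rest_interval[2]
  if (a < 1L || b > length(sleep_wake) || b < a)
    stop("rest interval out of record bounds")
  if (b - a + 1L > 1440L) stop("rest interval spans more than 24 h")
  s <- sleep_wake[a:b]
  tib <- length(s)
  clock_at <- function(i) if (is.null(clock_hours)) NA_real_ else
    clock_hours[a + i - 1L]
  r <- rle(s)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  pers <- which(r$values == 1L & r$lengths >= persistent)
  if (length(pers) == 0L) {
    return(data.frame(onset = NA_real_, offset = NA_real_,
                      midpoint = NA_real_, latency = tib, waso = 0,
                      duration = 0, time_in_bed = tib, efficiency = 0))
  }
  onset_i <- starts[pers[1]]
  offset_i <- max(which(s == 1L))
  duration <- sum(s == 1L)
  waso <- sum(s[onset_i:offset_i] == 0L)
  onset_h <- clock_at(onset_i)
  offset_h <- clock_at(offset_i)
  midpoint <- if (is.na(onset_h)) NA_real_ else
    (onset_h + ((offset_h - onset_h) %% 24) / 2) %% 24
  data.frame(onset = onset_h, offset = offset_h, midpoint = midpoint,
             latency = onset_i - 1L, waso = waso, duration = duration,
             time_in_bed = tib, efficiency = 100 * duration / tib)
}

#' Score a whole record into per-night summaries
#'
#' Convenience composition: epoch sleep/wake scoring, rest-interval
#' detection, and per-night summaries.
#'
#' @param record A gap-free [actigraphy_record] (trim and forward-fill
#'   first if needed).
#' @param config Configuration list.
#' @return `data.frame` of per-night summaries (one row per detected night)
#'   with `night`, `day_type` and the [summarize_night()] columns.
#' @export
score_record <- function(record, config = sleepmos_config()) {
  sw <- score_sleep_wake(record, config)
  rests <- detect_rest_intervals(record, config)
  t0 <- record$timestamp[1]
  h0 <- as.integer(format(t0, "%H")) + as.integer(format(t0, "%M")) / 60
  clock <- (h0 + (seq_along(sw) - 1L) / 60) %% 24
  if (nrow(rests) == 0L)
    return(cbind(data.frame(night = integer(0), day_type = character(0)),
                 summarize_night(c(1L, rep(1L, 9L)), c(1, 10))[0, ]))
  res <- lapply(seq_len(nrow(rests)), function(i) {
    s <- summarize_night(sw, c(rests$start[i], rests$end[i]), clock,
                         persistent = config$scoring$persistent_sleep_epochs)
    cbind(data.frame(night = rests$night[i], day_type = rests$day_type[i],
                     stringsAsFactors = FALSE), s)
  })
  do.call(rbind, res)
}

#' Map a nightly sleep component to a 0-3 subscore
#'
#' PSQI-style bands: worse values never receive a lower subscore.
#' Efficiency (percent): >= 85 is 0, 75-84 is 1, 65-74 is 2, below 65 is 3.
#' Latency (min): <= 15, 16-30, 31-60, > 60. WASO (min): <= 20, 21-40,
#' 41-60, > 60. Duration (min): >= 420, 360-419, 300-359, < 300. Bands are
#' configurable.
#'
#' @param component One of `"efficiency"`, `"latency"`, `"waso"`,
#'   `"duration"`.
#' @param value Component value (percent for efficiency, minutes otherwise).
#' @param config Configuration list (`scoring` block bands).
#' @return Integer subscore in 0-3.
#' @export
component_subscore <- function(component, value, config = sleepmos_config()) {
  sc <- config$scoring
  if (length(value) != 1L || is.na(value) || value < 0)
    stop("component value must be a single non-negative number")
  switch(component,
    efficiency = {
      if (value > 100) stop("efficiency cannot exceed 100 percent")
      b <- sc$efficiency_bands
      if (value >= b[1]) 0L else if (value >= b[2]) 1L else if (value >= b[3]) 2L else 3L
    },
    latency = {
      b <- sc$latency_bands
      if (value <= b[1]) 0L else if (value <= b[2]) 1L else if (value <= b[3]) 2L else 3L
    },
    waso = {
      b <- sc$waso_bands
      if (value <= b[1]) 0L else if (value <= b[2]) 1L else if (value <= b[3]) 2L else 3L
    },
    duration = {
      b <- sc$duration_bands
      if (value >= b[1]) 0L else if (value >= b[2]) 1L else if (value >= b[3]) 2L else 3L
    },
    stop("unknown component: ", component)
  )
}

#' Class maps for the two composite scores
#'
#' `sleep_qual_week_class()`: score below 5 is class 0 (Good), 5 through 8
#' class 1 (Average), above 8 class 2 (Poor). `sleep_cons_class()`: below
#' 50 is class 0 (Good), 50 up to (excluding) 200 class 1 (Average), 200 up
#' to (excluding) 400 class 2 (Poor), 400 and above class 3 (Very Poor).
#' The maps are exhaustive and mutually exclusive over the score ranges.
#'
#' @param score Numeric score (vectorised).
#' @return Integer class id(s).
#' @export
sleep_qual_week_class <- function(score) {
  ifelse(score < 5, 0L, ifelse(score <= 8, 1L, 2L))
}

#' @rdname sleep_qual_week_class
#' @export
sleep_cons_class <- function(score) {
  ifelse(score < 50, 0L, ifelse(score < 200, 1L, ifelse(score < 400, 2L, 3L)))
}

new_sleep_label <- function(metric, score, class_id, class_name, components) {
  structure(list(metric = metric, score = score, class_id = class_id,
                 class_name = class_name, components = components),
            class = "sleep_label")
}

#' @export
print.sleep_label <- function(x, ...) {
  cat(sprintf("<sleep_label> %s score %.2f -> class %d (%s)\n",
              x$metric, x$score, x$class_id, x$class_name))
  invisible(x)
}

#' Weekly sleep-quality score (0-12, lower is better)
#'
#' Averages each nightly component (efficiency, latency, WASO, duration)
#' over the available nights, maps each average through its 0-3 subscore
#' band ([component_subscore()]), and sums the four subscores. Classes:
#' score below 5 is class 0 (Good), 5 through 8 class 1 (Average), above 8
#' class 2 (Poor).
#'
#' @param nights `data.frame` of per-night summaries with columns
#'   `efficiency`, `latency`, `waso`, `duration` (e.g. from
#'   [score_record()]).
#' @param config Configuration list.
#' @return A `sleep_label` with the score, class, and the four subscores.
#' @export
sleep_qual_week <- function(nights, config = sleepmos_config()) {
  if (is.null(nights) || nrow(nights) < 1L)
    stop("sleep_qual_week needs at least one night")
  comp <- c(efficiency = mean(nights$efficiency),
            latency = mean(nights$latency),
            waso = mean(nights$waso),
            duration = mean(nights$duration))
  sub <- vapply(names(comp), function(k)
    component_subscore(k, unname(comp[k]), config), integer(1))
  score <- sum(sub)
  class_id <- sleep_qual_week_class(score)
  new_sleep_label("SleepQualWeek", score, class_id,
                  c("Good", "Average", "Poor")[class_id + 1L],
                  list(means = comp, subscores = sub))
}

#' Sleep-consistency score (lower is better)
#'
#' Weighted combination of three regularity components, all in minutes:
#' `score = w1 * SleepVar + w2 * WeekendDiff + w3 * MidpointVar` with
#' weights 0.4 / 0.3 / 0.3. SleepVar is the night-to-night standard
#' deviation of sleep duration; WeekendDiff the absolute circular
#' difference between mean weekday and mean weekend sleep midpoints (or the
#' absolute duration difference, configurable); MidpointVar the circular
#' standard deviation of the midpoint on the 24-hour wheel. Variance
#' (instead of SD) components are selectable via
#' `config$scoring$cons_dispersion = "var"`. Classes: below 50 is class 0
#' (Good), 50-200 class 1 (Average), 200-400 class 2 (Poor), 400 and above
#' class 3 (Very Poor).
#'
#' @param nights `data.frame` of per-night summaries with `duration` and
#'   `midpoint` columns.
#' @param day_types Character vector per night, `"weekday"` or `"weekend"`;
#'   defaults to `nights$day_type`. With no weekend (or no weekday) nights
#'   WeekendDiff is 0 with a warning.
#' @param config Configuration list.
#' @return A `sleep_label` with the score, class, and components.
#' @export
sleep_cons <- function(nights, day_types = nights$day_type,
                       config = sleepmos_config()) {
  if (is.null(nights) || nrow(nights) < 2L)
    stop("sleep_cons needs at least two nights")
  sc <- config$scoring
  ok <- !is.na(nights$duration) & !is.na(nights$midpoint)
  nights <- nights[ok, , drop = FALSE]
  day_types <- day_types[ok]
  if (nrow(nights) < 2L) stop("sleep_cons needs at least two scored nights")
  sleep_var <- stats::sd(nights$duration)
  midpoint_var <- circ_sd_minutes(nights$midpoint)
  wd <- day_types == "weekday"
  we <- day_types == "weekend"
  if (!any(wd) || !any(we)) {
    warning("no weekday/weekend contrast available; WeekendDiff set to 0")
    weekend_diff <- 0
  } else if (identical(sc$weekend_diff_mode, "duration")) {
    weekend_diff <- abs(mean(nights$duration[wd]) - mean(nights$duration[we]))
  } else {
    weekend_diff <- circ_diff_minutes(circ_mean_hours(nights$midpoint[wd]),
                                      circ_mean_hours(nights$midpoint[we]))
  }
  if (identical(sc$cons_dispersion, "var")) {
    sleep_var <- sleep_var^2
    midpoint_var <- midpoint_var^2
  }
  w <- sc$cons_weights
  score <- w[["sleep_var"]] * sleep_var + w[["weekend_diff"]] * weekend_diff +
    w[["midpoint_var"]] * midpoint_var
  class_id <- sleep_cons_class(score)
  new_sleep_label("SleepCons", score, class_id,
                  c("Good", "Average", "Poor", "VeryPoor")[class_id + 1L],
                  c(sleep_var = sleep_var, weekend_diff = weekend_diff,
                    midpoint_var = midpoint_var))
}
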