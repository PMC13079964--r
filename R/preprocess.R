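#' Trim leading and trailing off-wrist runs
#'
#' Removes the maximal run of off-wrist epochs at the start and at the end of
#' a record. Interior off-wrist epochs are retained as missing counts, to be
#' forward-filled downstream.
#'
#' @param record An [actigraphy_record].
#' @return The trimmed [actigraphy_record].
#' @export
trim_offwrist_edges <- function(record) {
  stopifnot(inherits(record, "actigraphy_record"))
  worn <- which(record$offwrist == 0L)
  if (length(worn) == 0L)
    stop("empty record: every epoch is off-wrist")
  keep <- seq.int(worn[1], worn[length(worn)])
  actigraphy_record(record$participant_id, record$timestamp[keep],
                    record$activity[keep], record$offwrist[keep])
}

#' Forward-fill missing counts
#'
#' Replaces every missing count by the most recent preceding valid count.
#' The record must start with a valid count (guaranteed after
#' [trim_offwrist_edges()] unless the first worn epoch itself has a recorded
#' gap).
#'
#' @param record An [actigraphy_record].
#' @return The gap-free [actigraphy_record].
#' @export
forward_fill <- function(record) {
  stopifnot(inherits(record, "actigraphy_record"))
  x <- record$activity
  if (is.na(x[1]))
    stop("state error: leading missing count; trim off-wrist edges first")
  if (anyNA(x)) {
    valid <- !is.na(x)
    x <- x[valid][cumsum(valid)]
  }
  record$activity <- x
  record
}

#' Downsample a gap-free record to hourly mean counts
#'
#' Each output value is the arithmetic mean of the 60 one-minute counts in
#' that hour. Hours are aligned to the record's first epoch by default
#' (avoiding the loss of up to 59 leading minutes); set
#' `clock_aligned = TRUE` to align bins to wall-clock hours instead. A
#' trailing partial hour is dropped.
#'
#' @param record A gap-free [actigraphy_record].
#' @param clock_aligned Align hour bins to wall-clock hours?
#' @return An object of class `hourly_series`: list with `participant_id`,
#'   `values` (hourly means), `start_time` (POSIXct of the first bin).
#' @export
downsample_hourly <- function(record, clock_aligned = FALSE) {
  stopifnot(inherits(record, "actigraphy_record"))
  if (anyNA(record$activity))
    stop("state error: record has missing counts; forward-fill first")
  x <- record$activity
  offset <- 0L
  if (clock_aligned) {
    min_of_hour <- as.integer(format(record$timestamp[1], "%M"))
    offset <- if (min_of_hour == 0L) 0L else (60L - min_of_hour)
    x <- x[seq_along(x) > offset]
  }
  n_hours <- length(x) %/% 60L
  if (n_hours < 1L)
    stop("too-short error: need at least 60 one-minute epochs per hour bin")
  x <- x[seq_len(n_hours * 60L)]
  vals <- colMeans(matrix(x, nrow = 60L))
  structure(list(participant_id = record$participant_id,
                 values = as.numeric(vals),
                 start_time = record$timestamp[offset + 1L]),
            class = "hourly_series")
}

#' @export
print.hourly_series <- function(x, ...) {
  cat("<hourly_series> participant", x$participant_id, "-",
      length(x$values), "hourly mean counts from", format(x$start_time), "\n")
  invisible(x)
}

#' Cut an hourly series into overlapping sliding windows
#'
#' Produces windows of `window_len` hourly samples advanced by `step` hours
#' (defaults: 24-hour windows, 12-hour step, i.e. 50 percent overlap), so a
#' 7-day series of 168 hours yields 13 windows.
#'
#' @param series An `hourly_series` from [downsample_hourly()].
#' @param window_len Window length in hours.
#' @param step Step between window starts in hours.
#' @return An object of class `window_set`: list with `windows` (matrix,
#'   one row per window), `start_hours` (0-based offset of each window),
#'   `participant_id`.
#' @export
make_windows <- function(series, window_len = 24L, step = 12L) {
  stopifnot(inherits(series, "hourly_series"))
  L <- length(series$values)
  if (L < window_len)
    stop("too-short error: series has ", L, " hours; need >= ", window_len)
  starts <- seq.int(0L, L - window_len, by = step)
  w <- t(vapply(starts, function(s) series$values[s + seq_len(window_len)],
                numeric(window_len)))
  structure(list(windows = w, start_hours = as.integer(starts),
                 participant_id = series$participant_id),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> participant", x$participant_id, "-", nrow(x$windows),
      "windows of", ncol(x$windows), "hourly samples (step",
      if (length(x$start_hours) > 1) diff(x$start_hours)[1] else NA, "h)\n")
  invisible(x)
}

#' Min-max normalise windowed activity to [0, 1]
#'
#' Scales values so the minimum maps to 0 and the maximum to 1, either over
#' the whole record (`per_record`, the default: preserves amplitude
#' differences between day- and night-dominated windows) or within each
#' window (`per_window`). Constant input maps to all zeros by convention.
#'
#' @param windows A `window_set`.
#' @param scope `"per_record"` or `"per_window"`.
#' @return The normalised `window_set`.
#' @export
minmax_normalize <- function(windows, scope = c("per_record", "per_window")) {
  stopifnot(inherits(windows, "window_set"))
  scope <- match.arg(scope)
  w <- windows$windows
  scale01 <- function(v) {
    r <- range(v)
    if (r[2] - r[1] <= 0) return(v * 0)
    (v - r[1]) / (r[2] - r[1])
  }
  windows$windows <- if (scope == "per_record") {
    matrix(scale01(as.numeric(w)), nrow = nrow(w), ncol = ncol(w))
  } else {
    t(apply(w, 1L, scale01))
  }
  windows
}

#' Run the full preprocessing chain on one record
#'
#' Fixed-order composition: trim off-wrist edges, forward-fill interior
#' gaps, downsample to hourly means, cut sliding windows, min-max normalise.
#'
#' @param record An [actigraphy_record].
#' @param config A configuration list (see [sleepmos_config()]); only the
#'   `preprocess` block is used.
#' @return A normalised `window_set`.
#' @export
preprocess_record <- function(record, config = sleepmos_config()) {
  pp <- config$preprocess
  record |>
    trim_offwrist_edges() |>
    forward_fill() |>
    downsample_hourly(clock_aligned = isTRUE(pp$clock_aligned_hours)) |>
    make_windows(window_len = pp$window_len, step = pp$step) |>
    minmax_normalize(scope = pp$norm_scope)
}
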