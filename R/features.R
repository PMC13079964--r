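#' Hand-crafted statistical features of a 24-hour window
#'
#' Three descriptors per window: the mean activity level, the standard
#' deviation (population denominator `n`, a descriptive summary of the fixed
#' window), and the zero percent - the proportion of hourly samples whose
#' activity is exactly zero, a marker of extended inactivity such as sleep.
#'
#' @param window Numeric vector of length 24 (one window), or a matrix with
#'   one window per row.
#' @return A named numeric vector `(mean, sd, zero_percent)`, or a matrix
#'   with those columns for matrix input.
#' @export
statistical_features <- function(window) {
  if (is.matrix(window)) {
    out <- t(apply(window, 1L, statistical_features))
    colnames(out) <- c("stat_mean", "stat_sd", "stat_zero_percent")
    return(out)
  }
  if (length(window) != 24L)
    stop("parameter error: window must have length 24, got ", length(window))
  n <- length(window)
  m <- mean(window)
  c(stat_mean = m,
    stat_sd = sqrt(sum((window - m)^2) / n),
    stat_zero_percent = sum(window == 0) / n)
}

#' Fuse deep and statistical feature blocks
#'
#' Column-wise concatenation with deep features first; column provenance
#' (`deep` vs `stat`) is recorded in the `provenance` attribute.
#'
#' @param deep Matrix of deep features (one row per window).
#' @param stat Matrix of statistical features with the same row count.
#' @return A `feature_matrix`: numeric matrix with attributes `provenance`
#'   (character per column) carrying the feature family of every column.
#' @export
fuse_features <- function(deep, stat) {
  if (!is.matrix(deep) || !is.matrix(stat)) stop("both blocks must be matrices")
  if (nrow(deep) == 0L || nrow(stat) == 0L)
    stop("parameter error: feature blocks must have at least one row")
  if (nrow(deep) != nrow(stat))
    stop("parameter error: row mismatch between deep (", nrow(deep),
         ") and stat (", nrow(stat), ") blocks")
  out <- cbind(deep, stat)
  attr(out, "provenance") <- c(rep("deep", ncol(deep)), rep("stat", ncol(stat)))
  class(out) <- c("feature_matrix", class(out))
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat("<feature_matrix>", nrow(x), "windows x", ncol(x), "features (",
      sum(pv == "deep"), "deep +", sum(pv == "stat"), "statistical )\n")
  invisible(x)
}

#' Build the fused feature matrix for a cohort
#'
#' Preprocesses every record, trains (or reuses) the LSTM extractor on the
#' pooled windows, computes deep and statistical features and fuses them.
#' Each window inherits its participant's class label.
#'
#' @param records List of [actigraphy_record] objects.
#' @param labels Named vector of participant-level class labels (names =
#'   participant ids).
#' @param metric `"SleepQualWeek"` or `"SleepCons"`; chooses the default
#'   extractor architecture.
#' @param config Configuration list.
#' @param extractor Optional pre-trained `lstm_extractor` to reuse.
#' @return List with `features` (a `feature_matrix`), `labels` (per
#'   window), `group` (participant id per window), `extractor`, and
#'   `windows` (the pooled normalised window matrix).
#' @export
build_feature_matrix <- function(records, labels,
                                 metric = c("SleepQualWeek", "SleepCons"),
                                 config = sleepmos_config(),
                                 extractor = NULL) {
  metric <- match.arg(metric)
  ws <- lapply(records, preprocess_record, config = config)
  X <- do.call(rbind, lapply(ws, function(w) w$windows))
  group <- unlist(lapply(ws, function(w)
    rep(w$participant_id, nrow(w$windows))), use.names = FALSE)
  y <- as.character(labels[group])
  if (anyNA(y)) stop("missing label for participant(s): ",
                     paste(unique(group[is.na(y)]), collapse = ", "))
  if (is.null(extractor)) {
    sizes <- if (metric == "SleepQualWeek")
      config$extractor$layer_sizes_SleepQualWeek
    else config$extractor$layer_sizes_SleepCons
    extractor <- train_extractor(X, y, layer_sizes = sizes, config = config)
  }
  deep <- extract_deep_features(extractor, X)
  stat <- statistical_features(X)
  list(features = fuse_features(deep, stat), labels = y, group = group,
       extractor = extractor, windows = X)
}
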