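# shared fixtures and brute-force oracles, all built in code

t_base <- as.POSIXct("2024-01-01 12:00", tz = "")

# minimal record from a count vector (1-min epochs starting at noon)
make_record <- function(counts, offwrist = rep(0L, length(counts)),
                        id = "T001", start = t_base) {
  actigraphy_record(id, start + 60 * (seq_along(counts) - 1L),
                    counts, offwrist)
}

# brute-force forward fill
ff_oracle <- function(x) {
  for (i in seq_along(x)) if (is.na(x[i]) && i > 1) x[i] <- x[i - 1]
  x
}

# brute-force hourly means by explicit 60-element loop
hourly_oracle <- function(x) {
  n <- length(x) %/% 60
  out <- numeric(n)
  for (h in seq_len(n)) {
    s <- 0
    for (j in 1:60) s <- s + x[(h - 1) * 60 + j]
    out[h] <- s / 60
  }
  out
}

# brute-force min-max scaling
minmax_oracle <- function(v) {
  if (max(v) == min(v)) return(v * 0)
  (v - min(v)) / (max(v) - min(v))
}

# low-noise generator profile used for parameter-recovery checks
low_noise_profile <- function() {
  sleep_profile(latency_mean = 10, waso_mean = 15, efficiency_target = 90,
                duration_sd = 20, midpoint_sd = 15, weekend_shift = 15,
                night_activity_mean = 0.1, count_dispersion = 0.3)
}

# quick extractor settings for tests that need a trained LSTM but not a
# converged one
fast_lstm_config <- function(cfg = sleepmos_config()) {
  cfg$extractor$epochs <- 8L
  cfg$extractor$patience <- 4L
  cfg
}

# small search budget for repeated-search experiments
small_search_config <- function(cfg = sleepmos_config()) {
  cfg$genetic$population <- 10L
  cfg$genetic$generations <- 8L
  cfg$pso$population <- 10L
  cfg$pso$iterations <- 8L
  cfg
}
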