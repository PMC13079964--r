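#' Default pipeline configuration
#'
#' Returns the full nested configuration used by every stage of the pipeline,
#' with defaults matching the published operating point of the method: hourly
#' downsampling with 24-hour windows stepped by 12 hours, min-max
#' normalisation over the whole record, a stacked LSTM extractor
#' (75-50-25-15 nodes for the weekly-quality target, 100-80-60-40 for the
#' consistency target, tanh activation, dropout 0.2), genetic-search
#' hyperparameters (crossover 0.6, mutation 0.033, population 20,
#' generations 20), geometric PSO recombination weights
#' (inertia 0.33, individual 0.34, social 0.33, population 20, iterations 20,
#' logistic-regression fitness), and a linear SVM with `C = 0.1` evaluated by
#' 10-fold grouped stratified cross-validation.
#'
#' @return A named nested list with components `preprocess`, `scoring`,
#'   `extractor`, `genetic`, `pso`, `svm`, `evaluation`, `importance`.
#' @export
#' @examples
#' cfg <- sleepmos_config()
#' cfg$genetic$crossover_prob
sleepmos_config <- function() {
  list(
    preprocess = list(
      window_len = 24L,
      step = 12L,
      norm_scope = "per_record",   # or "per_window"
      clock_aligned_hours = FALSE
    ),
    scoring = list(
      # Cole-Kripke style 1-minute weights, centre epoch index 5 of 7
      weights = c(106, 54, 58, 76, 230, 74, 67) / 1000,
      threshold = 1.0,
      webster_rescore = FALSE,
      persistent_sleep_epochs = 5L,
      # rest-interval detection: nightly search window and quiescence rule
      rest_search_start_hour = 18,  # 18:00 of day d ...
      rest_search_end_hour = 12,    # ... to 12:00 of day d + 1
      rest_smooth_epochs = 11L,
      rest_threshold_frac = 0.10,   # of the high-activity (day) level
      rest_threshold_min = 5,
      # component subscore bands (0-3 each, PSQI-style)
      efficiency_bands = c(85, 75, 65),   # >=85 -> 0; 75-84 -> 1; 65-74 -> 2; <65 -> 3
      latency_bands = c(15, 30, 60),      # <=15 -> 0; 16-30 -> 1; 31-60 -> 2; >60 -> 3
      waso_bands = c(20, 40, 60),         # <=20 -> 0; 21-40 -> 1; 41-60 -> 2; >60 -> 3
      duration_bands = c(420, 360, 300),  # >=420 -> 0; 360-419 -> 1; 300-359 -> 2; <300 -> 3
      # consistency score
      cons_weights = c(sleep_var = 0.4, weekend_diff = 0.3, midpoint_var = 0.3),
      cons_dispersion = "sd",             # "sd" (minutes) or "var"
      weekend_diff_mode = "midpoint"      # or "duration"
    ),
    extractor = list(
      layer_sizes_SleepQualWeek = c(75L, 50L, 25L, 15L),
      layer_sizes_SleepCons = c(100L, 80L, 60L, 40L),
      activation = "tanh",
      dropout = 0.2,
      epochs = 100L,
      batch_size = 32L,
      learning_rate = 1e-3,
      val_fraction = 0.1,
      patience = 10L,
      seed = 1L
    ),
    genetic = list(
      crossover_prob = 0.6,
      mutation_prob = 0.033,
      population = 20L,
      generations = 20L,
      report_frequency = 20L,
      seed = 1L,
      fitness_classifier = "svm",
      cv_folds = 5L
    ),
    pso = list(
      inertia_weight = 0.33,
      individual_weight = 0.34,
      social_weight = 0.33,
      population = 20L,
      iterations = 20L,
      fitness_classifier = "logistic",
      mutation_prob = NA_real_,   # NA -> 1 / n_features
      seed = 1L,
      cv_folds = 5L
    ),
    svm = list(C = 0.1),
    evaluation = list(
      folds = 10L,
      grouped = TRUE,
      seed = 1L
    ),
    importance = list(repeats = 10L, seed = 1L)
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a (possibly partial) YAML configuration and merges it over the
#' defaults from [sleepmos_config()]: any key not present in the file keeps
#' its default. The merged configuration is validated; violations raise an
#' error naming the offending key.
#'
#' @param path Path to a YAML file. `NULL` or a missing/empty file yields the
#'   pure defaults.
#' @return A validated configuration list (see [sleepmos_config()]).
#' @export
load_config <- function(path = NULL) {
  cfg <- sleepmos_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- modify_list_deep(cfg, user)
  }
  # YAML maps arrive as lists; flatten the keys that are numeric vectors
  for (k in c("weights", "cons_weights", "efficiency_bands", "latency_bands",
              "waso_bands", "duration_bands"))
    cfg$scoring[[k]] <- unlist(cfg$scoring[[k]])
  for (k in c("layer_sizes_SleepQualWeek", "layer_sizes_SleepCons"))
    cfg$extractor[[k]] <- as.integer(unlist(cfg$extractor[[k]]))
  validate_config(cfg)
  cfg
}

# recursive modifyList keeping nested defaults
modify_list_deep <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]])) {
      base[[k]] <- modify_list_deep(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  chk_prob <- function(x, key) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1))
      stop("config error: '", key, "' must lie in [0, 1]", call. = FALSE)
  }
  chk_pos <- function(x, key) {
    if (!is.numeric(x) || any(x < 1))
      stop("config error: '", key, "' must be a positive size", call. = FALSE)
  }
  chk_prob(cfg$genetic$crossover_prob, "genetic.crossover_prob")
  chk_prob(cfg$genetic$mutation_prob, "genetic.mutation_prob")
  chk_pos(cfg$genetic$population, "genetic.population")
  chk_pos(cfg$genetic$generations + 1L, "genetic.generations")
  w3 <- c(cfg$pso$inertia_weight, cfg$pso$individual_weight, cfg$pso$social_weight)
  chk_prob(w3, "pso weights")
  if (abs(sum(w3) - 1) > 1e-8)
    stop("config error: 'pso' weights (inertia, individual, social) must sum to 1",
         call. = FALSE)
  chk_pos(cfg$pso$population, "pso.population")
  cw <- cfg$scoring$cons_weights
  if (abs(sum(cw) - 1) > 1e-8)
    stop("config error: 'scoring.cons_weights' (w1, w2, w3) must sum to 1",
         call. = FALSE)
  if (any(cw < 0)) stop("config error: 'scoring.cons_weights' must be non-negative",
                        call. = FALSE)
  if (!is.numeric(cfg$svm$C) || cfg$svm$C <= 0)
    stop("config error: 'svm.C' must be > 0", call. = FALSE)
  dp <- cfg$extractor$dropout
  if (!is.numeric(dp) || dp < 0 || dp >= 1)
    stop("config error: 'extractor.dropout' must lie in [0, 1)", call. = FALSE)
  chk_pos(cfg$preprocess$window_len, "preprocess.window_len")
  chk_pos(cfg$preprocess$step, "preprocess.step")
  chk_pos(cfg$evaluation$folds, "evaluation.folds")
  invisible(cfg)
}
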