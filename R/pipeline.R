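#' Write a synthetic demonstration cohort to disk
#'
#' Generates the default cohort for the chosen metric (28 participants for
#' the weekly-quality target: 10 + 10 + 8 across classes 0/1/2; 40 for the
#' consistency target: 10 per class) and writes one epoch CSV per
#' participant plus a `ground_truth.csv` sidecar with per-night parameters
#' and the noiseless scores/classes. Deterministic for a fixed seed
#' (rerunning yields byte-identical files).
#'
#' @param metric `"SleepQualWeek"` or `"SleepCons"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Cohort seed.
#' @param n_days Days per participant.
#' @return Invisibly, a list with `epoch_files`, `ground_truth` (path) and
#'   `meta` (the cohort metadata `data.frame`).
#' @export
make_demo_dataset <- function(metric = c("SleepQualWeek", "SleepCons"),
                              out_dir, seed = 7, n_days = 7) {
  metric <- match.arg(metric)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir)
  cohort <- generate_cohort(metric = metric, n_days = n_days, seed = seed)
  paths <- vapply(names(cohort$records), function(pid) {
    p <- file.path(out_dir, paste0(pid, ".csv"))
    write_epochs(cohort$records[[pid]], p)
    p
  }, character(1))
  gt <- do.call(rbind, lapply(names(cohort$truth), function(pid) {
    tr <- cohort$truth[[pid]]
    meta <- cohort$meta[cohort$meta$participant_id == pid, ]
    data.frame(participant_id = pid, night_index = tr$night,
               day_type = tr$day_type,
               efficiency = round(tr$efficiency, 3), latency = tr$latency,
               waso = tr$waso, duration = tr$duration,
               midpoint = round(tr$midpoint, 4),
               sqw_score = meta$sqw_score, sqw_class = meta$sqw_class,
               cons_score = round(meta$cons_score, 3),
               cons_class = meta$cons_class, stringsAsFactors = FALSE)
  }))
  gt_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(gt, gt_path, row.names = FALSE, quote = FALSE)
  invisible(list(epoch_files = paths, ground_truth = gt_path,
                 meta = cohort$meta))
}

#' Run the full pipeline end to end
#'
#' Orchestrates the complete flow on a directory of epoch CSVs (or a
#' freshly generated demonstration cohort): read, preprocess, label
#' (ground-truth sidecar if present, else actigraphy scoring), extract and
#' fuse features, select, classify, cross-validate, and compute permutation
#' importance. All artifacts are written to `out_dir` together with a run
#' manifest (config snapshot, seeds, stage-by-stage sizes, output paths)
#' that fully determines a rerun. Outputs are written only after every
#' stage succeeded.
#'
#' @param input_dir Directory of simple-dialect epoch CSVs; `NULL`
#'   generates the demonstration cohort for `metric` with `seed` into
#'   `file.path(out_dir, "data")`.
#' @param metric `"SleepQualWeek"` or `"SleepCons"`.
#' @param out_dir Output directory for artifacts.
#' @param config Configuration list.
#' @param seed Master seed (fans out to all stages).
#' @param variant Pipeline variant (see [sleepmos()]).
#' @param label_source `"truth"` (use the `ground_truth.csv` sidecar) or
#'   `"scored"` (derive labels by scoring the records).
#' @return A list with `model` (the fitted [sleepmos()] object), `report`,
#'   `importance`, and `manifest`.
#' @export
run_pipeline <- function(input_dir = NULL,
                         metric = c("SleepQualWeek", "SleepCons"),
                         out_dir = tempfile("sleepmos_run_"),
                         config = sleepmos_config(), seed = 7,
                         variant = "full",
                         label_source = c("truth", "scored")) {
  metric <- match.arg(metric)
  label_source <- match.arg(label_source)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  tryCatch({
    if (is.null(input_dir)) {
      input_dir <- file.path(out_dir, "data")
      make_demo_dataset(metric, input_dir, seed = seed)
    }
    if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
    files <- setdiff(list.files(input_dir, pattern = "\\.csv(\\.gz)?$",
                                full.names = TRUE),
                     file.path(input_dir, "ground_truth.csv"))
    if (length(files) == 0L) stop("no epoch CSVs in ", input_dir)
    records <- lapply(files, read_epochs, dialect = "simple")
    names(records) <- vapply(records, `[[`, character(1), "participant_id")

    stage <- "labels"
    gt_path <- file.path(input_dir, "ground_truth.csv")
    if (label_source == "truth" && file.exists(gt_path)) {
      gt <- utils::read.csv(gt_path, stringsAsFactors = FALSE)
      col <- if (metric == "SleepQualWeek") "sqw_class" else "cons_class"
      lab <- tapply(gt[[col]], gt$participant_id, function(v) v[1])
      labels <- stats::setNames(as.character(lab), names(lab))
    } else {
      labels <- score_cohort_labels(records, metric, config)
    }

    stage <- "fit"
    model <- sleepmos(records, labels, metric = metric, config = config,
                      variant = variant, seed = seed,
                      importance = variant != "pure_lstm")

    stage <- "outputs"
    rp <- file.path(out_dir, "report.json")
    jsonlite::write_json(report_as_list(model$report), rp,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ip <- NULL
    if (!is.null(model$importance)) {
      ip <- file.path(out_dir, "importance.csv")
      utils::write.csv(as.data.frame(model$importance), ip, row.names = FALSE)
    }
    mp <- NULL
    if (!is.null(model$subsets)) {
      mp <- file.path(out_dir, "selected_features.json")
      jsonlite::write_json(list(
        genetic = which(model$subsets$genetic$mask),
        pso = which(model$subsets$pso$mask),
        union = which(model$subsets$union$mask),
        genetic_fitness = model$subsets$genetic$fitness,
        pso_fitness = model$subsets$pso$fitness), mp,
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("sleepmos")),
      timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
      metric = metric, variant = variant, seed = seed,
      selection_stage_run = !is.null(model$subsets),
      input_dir = normalizePath(input_dir),
      n_participants = length(records),
      n_windows = model$n_windows %||% NA,
      n_features = length(model$feature_names %||% character(0)),
      config = config,
      outputs = list(report = rp, importance = ip, selected_features = mp),
      elapsed_seconds = model$elapsed)
    mf <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(model = model, report = model$report,
         importance = model$importance, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

report_as_list <- function(rep) {
  list(classifier = rep$classifier, folds = rep$folds, seed = rep$seed,
       accuracy = rep$accuracy,
       macro = as.list(rep$macro), weighted = as.list(rep$weighted),
       auc_macro = rep$auc_macro,
       auc_per_class = as.list(rep$auc_per_class),
       per_fold_accuracy = rep$per_fold,
       participant_accuracy = rep$participant$accuracy,
       confusion = as.data.frame.matrix(rep$confusion))
}
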