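#' Fit the hybrid sleep-quality model on an actigraphy cohort
#'
#' End-to-end fit of the hybrid pipeline on a cohort of epoch-level
#' actigraphy records: preprocessing (trim, forward fill, hourly
#' downsampling, 24-h sliding windows, min-max normalisation), stacked-LSTM
#' deep feature extraction, statistical features, dual metaheuristic
#' wrapper feature selection over the deep block (genetic algorithm and
#' geometric PSO, combined by union), and a linear SVM (`C = 0.1`) on the
#' fused selected features. The fit is evaluated by grouped stratified
#' 10-fold cross-validation (all windows of a participant stay in one
#' fold) and permutation feature importance is computed on the held-out
#' folds.
#'
#' @param records Named list of [actigraphy_record] objects.
#' @param labels Named vector (participant id -> class label). If `NULL`,
#'   labels are derived by scoring each record ([score_record()]) and
#'   applying the chosen metric.
#' @param metric `"SleepQualWeek"` (3 classes) or `"SleepCons"`
#'   (4 classes).
#' @param config Configuration list, see [sleepmos_config()].
#' @param variant Pipeline variant: `"full"` (default), or an ablation:
#'   `"no_optimization"` (skip metaheuristic selection),
#'   `"no_stat_features"` (deep features only), `"pure_lstm"`
#'   (end-to-end softmax-head LSTM, no SVM), `"random_forest"` or
#'   `"gradient_boosting"` (tree classifiers on the full fused features).
#' @param seed Optional master seed; when given it fans out to per-stage
#'   seeds (extractor, searches, evaluation, importance) so one knob
#'   reproduces the whole run.
#' @param importance Compute permutation importance? (Skipped for
#'   `pure_lstm`.)
#' @return An object of class `sleepmos` with `print`, `summary`,
#'   `predict`, `plot` and `coef` methods.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(metric = "SleepQualWeek", seed = 7)
#' labels <- setNames(cohort$meta$sqw_class, cohort$meta$participant_id)
#' cfg <- sleepmos_config()
#' cfg$extractor$epochs <- 10L  # quick demonstration fit
#' fit <- sleepmos(cohort$records, labels, config = cfg, seed = 7)
#' print(fit)
#' }
sleepmos <- function(records, labels = NULL,
                     metric = c("SleepQualWeek", "SleepCons"),
                     config = sleepmos_config(), variant = "full",
                     seed = NULL, importance = TRUE) {
  metric <- match.arg(metric)
  variant <- match.arg(variant, c("full", "no_optimization",
                                  "no_stat_features", "pure_lstm",
                                  "random_forest", "gradient_boosting"))
  if (!is.null(seed)) config <- fan_out_seeds(config, seed)
  validate_config(config)
  if (is.null(labels)) labels <- score_cohort_labels(records, metric, config)
  prepared <- build_feature_matrix(records, labels, metric, config)
  fit_prepared(prepared, metric, config, variant, importance)
}

fan_out_seeds <- function(config, seed) {
  seed <- as.integer(seed)
  config$extractor$seed <- seed + 101L
  config$genetic$seed <- seed + 202L
  config$pso$seed <- seed + 303L
  config$evaluation$seed <- seed + 404L
  config$importance$seed <- seed + 505L
  config
}

score_cohort_labels <- function(records, metric, config = sleepmos_config()) {
  lab <- vapply(records, function(r) {
    rec <- forward_fill(trim_offwrist_edges(r))
    nights <- score_record(rec, config)
    if (metric == "SleepQualWeek") sleep_qual_week(nights, config)$class_id
    else sleep_cons(nights, config = config)$class_id
  }, integer(1))
  stats::setNames(as.character(lab), names(records))
}

# core fit on a prepared feature set (see build_feature_matrix)
fit_prepared <- function(prepared, metric, config, variant = "full",
                         importance = TRUE) {
  t0 <- Sys.time()
  feats <- prepared$features
  prov <- attr(feats, "provenance")
  deep <- unclass_matrix(feats)[, prov == "deep", drop = FALSE]
  stat <- unclass_matrix(feats)[, prov == "stat", drop = FALSE]
  y <- prepared$labels
  group <- prepared$group
  subsets <- NULL
  use_selection <- variant %in% c("full", "no_stat_features")
  use_stat <- !(variant %in% c("no_stat_features"))
  if (variant == "pure_lstm") {
    report <- cv_pure_lstm(prepared, config)
    obj <- structure(list(metric = metric, variant = variant,
                          config = config, classes = sort(unique(y)),
                          extractor = prepared$extractor, subsets = NULL,
                          feature_names = NULL, svm = NULL, report = report,
                          importance = NULL,
                          elapsed = as.numeric(difftime(Sys.time(), t0,
                                                        units = "secs"))),
                     class = "sleepmos")
    return(obj)
  }
  if (use_selection) {
    gsub_ <- genetic_search(deep, y, config)
    psub <- pso_search(deep, y, config)
    usub <- subset_union(gsub_, psub)
    subsets <- list(genetic = gsub_, pso = psub, union = usub)
    deep_sel <- deep[, usub$mask, drop = FALSE]
  } else {
    deep_sel <- deep
  }
  Xfin <- if (use_stat) fuse_features(deep_sel, stat) else {
    out <- deep_sel
    attr(out, "provenance") <- rep("deep", ncol(out))
    class(out) <- c("feature_matrix", class(out))
    out
  }
  clf_kind <- switch(variant, random_forest = "random_forest",
                     gradient_boosting = "gradient_boosting", "svm")
  ev <- config$evaluation
  report <- cross_validate(Xfin, y, group = if (isTRUE(ev$grouped)) group,
                           folds = ev$folds, seed = ev$seed,
                           classifier = clf_kind, C = config$svm$C)
  final <- fit_any_classifier(unclass_matrix(Xfin), y, clf_kind,
                              C = config$svm$C, seed = ev$seed)
  imp <- NULL
  if (isTRUE(importance))
    imp <- cv_importance(Xfin, y, group, config, clf_kind)
  structure(list(metric = metric, variant = variant, config = config,
                 classes = sort(unique(y)), extractor = prepared$extractor,
                 subsets = subsets,
                 feature_names = colnames(unclass_matrix(Xfin)),
                 provenance = attr(Xfin, "provenance"),
                 svm = final, report = report, importance = imp,
                 n_windows = nrow(Xfin), n_participants = length(unique(group)),
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "sleepmos")
}

# permutation importance aggregated over held-out CV folds
cv_importance <- function(X, y, group, config, clf_kind = "svm") {
  ev <- config$evaluation
  fa <- suppressWarnings(make_folds(y, group, ev$folds, ev$seed))
  prov <- attr(X, "provenance")
  Xu <- unclass_matrix(X)
  vals <- list(); base <- numeric(0)
  for (f in seq_len(fa$folds)) {
    tr <- fa$fold != f
    model <- fit_any_classifier(Xu[tr, , drop = FALSE], y[tr], clf_kind,
                                C = config$svm$C, seed = ev$seed + f)
    Xte <- Xu[!tr, , drop = FALSE]
    attr(Xte, "provenance") <- prov
    it <- permutation_importance(model, Xte, y[!tr],
                                 repeats = config$importance$repeats,
                                 seed = config$importance$seed + f)
    vals[[f]] <- it$importance
    base <- c(base, attr(it, "baseline"))
  }
  m <- do.call(rbind, vals)
  means <- colMeans(m)
  nm <- colnames(Xu)
  ord <- order(-means, nm)
  rank <- integer(ncol(Xu)); rank[ord] <- seq_len(ncol(Xu))
  out <- data.frame(feature = nm, provenance = prov, importance = means,
                    sd = apply(m, 2L, stats::sd), rank = rank,
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- mean(base)
  attr(out, "repeats") <- config$importance$repeats
  class(out) <- c("importance_table", class(out))
  out
}

# grouped CV for the end-to-end softmax-head LSTM baseline
cv_pure_lstm <- function(prepared, config) {
  y <- prepared$labels
  group <- prepared$group
  X <- prepared$windows
  ev <- config$evaluation
  fa <- make_folds(y, group, ev$folds, ev$seed)
  classes <- sort(unique(y))
  pred <- character(length(y))
  scores <- matrix(NA_real_, length(y), length(classes),
                   dimnames = list(NULL, classes))
  per_fold <- numeric(fa$folds)
  layer_sizes <- prepared$extractor$layer_sizes
  for (f in seq_len(fa$folds)) {
    tr <- fa$fold != f
    cfg_f <- config
    cfg_f$extractor$seed <- config$extractor$seed + f
    ex <- train_extractor(X[tr, , drop = FALSE], y[tr],
                          layer_sizes = layer_sizes, config = cfg_f)
    pr <- predict_lstm_head(ex, X[!tr, , drop = FALSE])
    pred[!tr] <- pr$class
    scores[!tr, colnames(pr$prob)] <- pr$prob
    per_fold[f] <- mean(pr$class == y[!tr])
  }
  m <- compute_metrics(y, pred, scores)
  rep <- c(m, list(per_fold = per_fold, folds = fa$folds,
                   seed = ev$seed, classifier = "pure_lstm",
                   window_pred = pred,
                   participant = participant_vote(pred, y, group, classes)))
  structure(rep, class = "eval_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one pipeline variant on a prepared feature set
#'
#' Each variant toggles exactly one component of the full pipeline:
#' `pure_lstm` classifies end-to-end with the LSTM softmax head (retrained
#' per CV fold); `no_optimization` skips metaheuristic feature selection;
#' `no_stat_features` drops the hand-crafted statistical features; the tree
#' baselines (`random_forest`, `gradient_boosting`) consume the same fused
#' feature matrix as the full model, without selection.
#'
#' @param variant One of `"full"`, `"pure_lstm"`, `"no_optimization"`,
#'   `"no_stat_features"`, `"random_forest"`, `"gradient_boosting"`.
#' @param prepared Output of [build_feature_matrix()].
#' @param config Configuration list.
#' @param metric Metric name recorded on the underlying fit.
#' @return An `eval_report` (cross-validated).
#' @export
run_variant <- function(variant, prepared, config = sleepmos_config(),
                        metric = "SleepQualWeek") {
  variant <- match.arg(variant, c("full", "no_optimization",
                                  "no_stat_features", "pure_lstm",
                                  "random_forest", "gradient_boosting"))
  fit <- fit_prepared(prepared, metric = metric, config = config,
                      variant = variant, importance = FALSE)
  fit$report
}

#' @export
print.sleepmos <- function(x, ...) {
  cat("<sleepmos> hybrid LSTM + metaheuristic-selection + SVM model\n")
  cat("  metric:", x$metric, "| variant:", x$variant, "|",
      length(x$classes), "classes\n")
  if (!is.null(x$n_windows))
    cat("  fitted on", x$n_windows, "windows from", x$n_participants,
        "participants\n")
  if (!is.null(x$subsets))
    cat(sprintf("  selected deep features: GA %d, PSO %d, union %d of %d\n",
                sum(x$subsets$genetic$mask), sum(x$subsets$pso$mask),
                sum(x$subsets$union$mask), length(x$subsets$union$mask)))
  cat(sprintf("  CV accuracy %.3f | macro F1 %.3f | macro AUC %s",
              x$report$accuracy, x$report$macro[["f1"]],
              ifelse(is.na(x$report$auc_macro), "NA",
                     sprintf("%.3f", x$report$auc_macro))))
  if (!is.null(x$report$participant))
    cat(sprintf(" | participant accuracy %.3f", x$report$participant$accuracy))
  cat("\n")
  invisible(x)
}

#' @export
summary.sleepmos <- function(object, ...) {
  print(object)
  cat("\nCross-validated report:\n")
  print(object$report)
  if (!is.null(object$importance)) {
    cat("\nTop features by held-out permutation importance:\n")
    print.data.frame(rank_features(object$importance, 8L), row.names = FALSE)
  }
  invisible(object)
}

#' Predict sleep-quality classes for new records or windows
#'
#' @param object A fitted `sleepmos` model.
#' @param newdata Either a named list of [actigraphy_record] objects or a
#'   numeric window matrix (24 normalised hourly counts per row).
#' @param level `"participant"` (majority vote over a record's windows;
#'   requires records) or `"window"`.
#' @param ... Unused.
#' @return Named character vector of predicted classes.
#' @export
predict.sleepmos <- function(object, newdata,
                             level = c("participant", "window"), ...) {
  level <- match.arg(level)
  if (object$variant == "pure_lstm") {
    wins <- newdata_windows(object, newdata)
    pr <- predict_lstm_head(object$extractor, wins$X)$class
  } else {
    wins <- newdata_windows(object, newdata)
    deep <- extract_deep_features(object$extractor, wins$X)
    if (!is.null(object$subsets))
      deep <- deep[, object$subsets$union$mask, drop = FALSE]
    Xf <- if (any(object$provenance == "stat"))
      cbind(deep, statistical_features(wins$X)) else deep
    pr <- predict_any(object$svm, Xf)$class
  }
  if (level == "window" || is.null(wins$group)) {
    return(stats::setNames(pr, wins$group))
  }
  res <- participant_vote(pr, pr, wins$group, object$classes)
  stats::setNames(res$pred, sort(unique(wins$group)))
}

newdata_windows <- function(object, newdata) {
  if (is.matrix(newdata)) return(list(X = newdata, group = NULL))
  ws <- lapply(newdata, preprocess_record, config = object$config)
  list(X = do.call(rbind, lapply(ws, function(w) w$windows)),
       group = unlist(lapply(ws, function(w)
         rep(w$participant_id, nrow(w$windows))), use.names = FALSE))
}

#' @export
plot.sleepmos <- function(x, type = c("importance", "fitness"), ...) {
  type <- match.arg(type)
  if (type == "importance") {
    if (is.null(x$importance)) stop("model was fitted without importance")
    plot(x$importance, ...)
  } else {
    if (is.null(x$subsets)) stop("model was fitted without feature selection")
    ga <- x$subsets$genetic$log
    ps <- x$subsets$pso$log
    ylim <- range(c(ga$best, ga$mean, ps$best, ps$mean))
    graphics::plot(ga$generation, ga$best, type = "s", col = "steelblue",
                   lwd = 2, ylim = ylim, xlab = "generation / iteration",
                   ylab = "wrapper fitness (CV accuracy)", ...)
    graphics::lines(ga$generation, ga$mean, lty = 2, col = "steelblue")
    graphics::lines(ps$iteration, ps$best, type = "s", col = "tan2", lwd = 2)
    graphics::lines(ps$iteration, ps$mean, lty = 2, col = "tan2")
    graphics::legend("bottomright", c("GA best", "GA mean", "PSO best",
                                      "PSO mean"),
                     col = c("steelblue", "steelblue", "tan2", "tan2"),
                     lty = c(1, 2, 1, 2), lwd = c(2, 1, 2, 1), bty = "n")
  }
  invisible(x)
}

#' Linear SVM weights of the fitted model
#'
#' Reconstructs the primal weight vector of each one-vs-rest linear SVM
#' from its support vectors, one row per class (on the internally
#' standardised feature scale).
#'
#' @param object A fitted `sleepmos` model with an SVM final stage.
#' @param ... Unused.
#' @return Matrix of weights, classes by features.
#' @export
coef.sleepmos <- function(object, ...) {
  if (is.null(object$svm) || !inherits(object$svm, "sleepmos_svm"))
    stop("final classifier is not a linear SVM for this variant")
  W <- t(vapply(object$svm$models, function(m)
    as.numeric(t(m$coefs) %*% m$SV), numeric(object$svm$n_features)))
  rn <- if (length(object$svm$classes) == 2L) object$svm$classes[1]
        else object$svm$classes
  dimnames(W) <- list(rn, object$feature_names)
  W
}
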