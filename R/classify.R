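#' Train a linear SVM (one-vs-rest for multi-class)
#'
#' Linear-kernel support vector machine with regularisation parameter
#' `C = 0.1`. Features are standardised internally (constant columns left
#' untouched). With more than two classes, one binary SVM is fitted per
#' class against the rest and prediction takes the class with the largest
#' decision score.
#'
#' @param X Numeric feature matrix, one row per window; no missing cells.
#' @param y Class labels (>= 2 distinct values).
#' @param C Regularisation parameter, > 0.
#' @return An object of class `sleepmos_svm`.
#' @export
train_svm <- function(X, y, C = 0.1) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("parameter error: C must be a single value > 0")
  X <- unclass_matrix(X)
  if (anyNA(X)) stop("feature matrix contains missing cells")
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("parameter error: need at least 2 classes to train")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  fit_bin <- function(yy) {
    e1071::svm(Xs, factor(yy, levels = c("rest", "pos")), kernel = "linear",
               cost = C, scale = FALSE)
  }
  if (length(classes) == 2L) {
    models <- list(fit_bin(ifelse(y == classes[1], "pos", "rest")))
  } else {
    models <- lapply(classes, function(k)
      fit_bin(ifelse(y == k, "pos", "rest")))
  }
  structure(list(models = models, classes = classes, center = ctr,
                 scale = scl, C = C, n_features = ncol(X)),
            class = "sleepmos_svm")
}

unclass_matrix <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  attr(X, "provenance") <- NULL
  class(X) <- setdiff(class(X), "feature_matrix")
  X
}

# decision scores, one column per class (positive favours the class)
svm_scores <- function(model, X) {
  X <- unclass_matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature dimension mismatch: model expects ", model$n_features)
  Xs <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  get_d <- function(m) {
    p <- stats::predict(m, Xs, decision.values = TRUE)
    d <- as.numeric(attr(p, "decision.values"))
    # orient so that positive favours the "pos" level
    if (grepl("^pos/", colnames(attr(p, "decision.values"))[1])) d else -d
  }
  if (length(model$classes) == 2L) {
    d <- get_d(model$models[[1]])
    s <- cbind(d, -d)
  } else {
    s <- vapply(model$models, get_d, numeric(nrow(Xs)))
    if (!is.matrix(s)) s <- matrix(s, nrow = 1L)
  }
  colnames(s) <- model$classes
  s
}

#' @export
predict.sleepmos_svm <- function(object, newdata, ...) {
  s <- svm_scores(object, newdata)
  object$classes[max.col(s, ties.method = "first")]
}

#' @export
print.sleepmos_svm <- function(x, ...) {
  cat("<sleepmos_svm> linear SVM, C =", x$C, "-", length(x$classes),
      "classes,", x$n_features, "features\n")
  invisible(x)
}

# internal fast classifier dispatch used by wrapper feature selection;
# logistic = one-vs-rest logistic regression via glm.fit (no formula
# overhead - wrapper search evaluates thousands of subsets)
fit_wrapper_classifier <- function(X, y, classifier = c("svm", "logistic"),
                                   C = 0.1) {
  classifier <- match.arg(classifier)
  if (classifier == "svm") return(train_svm(X, y, C = C))
  X <- unclass_matrix(X)
  classes <- sort(unique(as.character(y)))
  Xi <- cbind(1, X)
  coefs <- vapply(if (length(classes) == 2L) classes[1] else classes,
    function(k) {
      fit <- suppressWarnings(stats::glm.fit(Xi, as.numeric(y == k),
                                             family = stats::binomial()))
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      cf
    }, numeric(ncol(Xi)))
  structure(list(coefs = coefs, classes = classes),
            class = "wrapper_logit")
}

#' @export
predict.wrapper_logit <- function(object, newdata, ...) {
  s <- cbind(1, unclass_matrix(newdata)) %*% object$coefs
  if (length(object$classes) == 2L) {
    object$classes[1L + as.integer(s[, 1] < 0)]
  } else {
    object$classes[max.col(s, ties.method = "first")]
  }
}

#' Classification metrics from held-out predictions
#'
#' Computes accuracy, per-class precision/recall/F1 with macro and weighted
#' (support-proportional) averages, the confusion matrix, and - when
#' decision scores are supplied - one-vs-rest AUC per class with a macro
#' average.
#'
#' @param truth True class labels.
#' @param pred Predicted class labels.
#' @param scores Optional numeric matrix of decision scores, one column per
#'   class (column names = class labels).
#' @return List with `accuracy`, `confusion` (rows = truth), `per_class`
#'   (`data.frame`), `macro` and `weighted` (named vectors of precision,
#'   recall, f1), `auc_per_class`, `auc_macro`.
#' @export
compute_metrics <- function(truth, pred, scores = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(c(truth, pred)))
  cm <- table(factor(truth, classes), factor(pred, classes))
  acc <- sum(diag(cm)) / sum(cm)
  support <- rowSums(cm)
  prec <- diag(cm) / pmax(colSums(cm), 1e-12)
  rec <- diag(cm) / pmax(support, 1e-12)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- data.frame(class = classes, support = as.integer(support),
                          precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1))
  macro <- c(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
  wts <- support / sum(support)
  weighted <- c(precision = sum(prec * wts), recall = sum(rec * wts),
                f1 = sum(f1 * wts))
  auc_pc <- NULL; auc_macro <- NA_real_
  if (!is.null(scores)) {
    auc_pc <- vapply(classes, function(k) {
      resp <- truth == k
      if (length(unique(resp)) < 2L || !(k %in% colnames(scores)))
        return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, scores[, k], quiet = TRUE,
                                     levels = c(FALSE, TRUE),
                                     direction = "<")))
    }, numeric(1))
    auc_macro <- mean(auc_pc, na.rm = TRUE)
  }
  list(accuracy = acc, confusion = cm, per_class = per_class, macro = macro,
       weighted = weighted, auc_per_class = auc_pc, auc_macro = auc_macro)
}

# grouped stratified fold assignment; returns integer fold id per row
make_folds <- function(y, group = NULL, folds = 10L, seed = 1L) {
  if (is.null(group)) {
    # ungrouped fast path: every row is its own group
    gy <- as.character(y)
    names(gy) <- as.character(seq_along(y))
    group <- names(gy)
  } else {
    gy <- vapply(split(as.character(y), group), function(v)
      names(which.max(table(v))), character(1))
  }
  gnames <- names(gy)
  min_per_class <- min(table(gy))
  folds_eff <- as.integer(min(folds, min_per_class))
  if (folds_eff < folds)
    warning("folds reduced from ", folds, " to ", folds_eff,
            " (smallest class has ", min_per_class, " groups)")
  if (folds_eff < 2L) stop("not enough groups per class for cross-validation")
  gfold <- integer(length(gnames)); names(gfold) <- gnames
  withr::with_seed(as.integer(seed), {
    offset <- 0L
    for (k in unique(gy)) {
      ix <- sample(gnames[gy == k])
      gfold[ix] <- ((seq_along(ix) - 1L + offset) %% folds_eff) + 1L
      offset <- offset + length(ix)
    }
  })
  list(fold = gfold[as.character(group)], folds = folds_eff)
}

#' Cross-validated evaluation of a classifier on a feature matrix
#'
#' Stratified k-fold cross-validation (default 10 folds), grouped by
#' participant when a `group` vector is given so that all windows of one
#' participant stay in one fold (window-level splitting would leak
#' participant identity). Metrics are aggregated over the pooled held-out
#' predictions; a per-fold accuracy table is retained. When grouped, a
#' participant-level report is also computed by majority vote over each
#' participant's window predictions (ties resolved towards the worst
#' class).
#'
#' @param X Feature matrix (no missing cells).
#' @param y Labels per row.
#' @param group Optional participant id per row.
#' @param folds Number of folds (reduced with a warning when a class has
#'   fewer groups).
#' @param seed Seed controlling fold assignment.
#' @param classifier `"svm"` (linear, `C` below), `"logistic"`,
#'   `"random_forest"` or `"gradient_boosting"`.
#' @param C SVM regularisation parameter.
#' @return An object of class `eval_report`: the [compute_metrics()] fields
#'   plus `per_fold`, `folds`, `seed`, `classifier` and (when grouped)
#'   `participant` (a list with `accuracy`, `truth`, `pred`).
#' @export
cross_validate <- function(X, y, group = NULL, folds = 10L, seed = 1L,
                           classifier = "svm", C = 0.1) {
  X <- unclass_matrix(X)
  y <- as.character(y)
  fa <- make_folds(y, group, folds, seed)
  fold <- fa$fold
  pred <- character(length(y))
  classes <- sort(unique(y))
  scores <- matrix(NA_real_, length(y), length(classes),
                   dimnames = list(NULL, classes))
  per_fold <- numeric(fa$folds)
  for (f in seq_len(fa$folds)) {
    tr <- fold != f; te <- fold == f
    model <- fit_any_classifier(X[tr, , drop = FALSE], y[tr], classifier, C,
                                seed = seed + f)
    pr <- predict_any(model, X[te, , drop = FALSE])
    pred[te] <- pr$class
    if (!is.null(pr$scores))
      scores[te, colnames(pr$scores)] <- pr$scores
    per_fold[f] <- mean(pr$class == y[te])
  }
  have_scores <- !anyNA(scores)
  m <- compute_metrics(y, pred, if (have_scores) scores else NULL)
  rep <- c(m, list(per_fold = per_fold, folds = fa$folds, seed = seed,
                   classifier = classifier, window_pred = pred))
  if (!is.null(group)) {
    agg <- participant_vote(pred, y, group, classes)
    rep$participant <- agg
  }
  structure(rep, class = "eval_report")
}

# worst class = highest label in sort order (labels encode increasing severity)
participant_vote <- function(pred, y, group, classes) {
  gl <- tapply(y, group, function(v) names(which.max(table(v))))
  gp <- tapply(pred, group, function(v) {
    tb <- table(factor(v, classes))
    winners <- names(tb)[tb == max(tb)]
    winners[length(winners)]
  })
  gp <- as.character(gp[names(gl)])
  gl <- as.character(gl)
  list(accuracy = mean(gp == gl), truth = gl, pred = gp)
}

fit_any_classifier <- function(X, y, classifier, C = 0.1, seed = 1L) {
  switch(classifier,
    svm = train_svm(X, y, C = C),
    logistic = fit_wrapper_classifier(X, y, "logistic"),
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("randomForest package required for the random_forest variant")
      withr::with_seed(as.integer(seed),
        structure(list(fit = randomForest::randomForest(
          unclass_matrix(X), factor(y), ntree = 100L),
          classes = sort(unique(y))), class = "rf_clf"))
    },
    gradient_boosting = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("xgboost package required for the gradient_boosting variant")
      classes <- sort(unique(y))
      fit <- withr::with_seed(as.integer(seed),
        xgboost::xgboost(unclass_matrix(X), factor(y, levels = classes),
                         nrounds = 100L, max_depth = 3L,
                         learning_rate = 0.1, nthreads = 1L, verbosity = 0))
      structure(list(fit = fit, classes = classes), class = "xgb_clf")
    },
    stop("unknown classifier: ", classifier)
  )
}

predict_any <- function(model, X) {
  if (inherits(model, "sleepmos_svm")) {
    s <- svm_scores(model, X)
    list(class = model$classes[max.col(s, ties.method = "first")], scores = s)
  } else if (inherits(model, "wrapper_logit")) {
    list(class = predict(model, X), scores = NULL)
  } else if (inherits(model, "rf_clf")) {
    p <- stats::predict(model$fit, unclass_matrix(X), type = "prob")
    list(class = colnames(p)[max.col(p, ties.method = "first")], scores = p)
  } else if (inherits(model, "xgb_clf")) {
    p <- stats::predict(model$fit, unclass_matrix(X), type = "response")
    if (!is.matrix(p))       # binary: probability of the second level
      p <- cbind(1 - p, p)
    colnames(p) <- model$classes
    list(class = model$classes[max.col(p, ties.method = "first")], scores = p)
  } else stop("unknown model type")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$classifier, "-", x$folds, "fold CV\n")
  cat(sprintf("  accuracy %.4f | macro F1 %.4f | weighted F1 %.4f | macro AUC %s\n",
              x$accuracy, x$macro[["f1"]], x$weighted[["f1"]],
              ifelse(is.na(x$auc_macro), "NA", sprintf("%.4f", x$auc_macro))))
  if (!is.null(x$participant))
    cat(sprintf("  participant-level accuracy %.4f (majority vote)\n",
                x$participant$accuracy))
  cat("  confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
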