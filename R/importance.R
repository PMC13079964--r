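#' Permutation feature importance
#'
#' For each feature, importance is the baseline held-out score minus the
#' mean score after randomly shuffling that feature's column (breaking its
#' association with the label) while leaving every other column intact:
#' `importance_f = baseline - mean(score after permuting f)`. The baseline
#' is computed once; shuffles are seeded and repeated (default 10 times)
#' so an SD per feature is available. Supply held-out data (e.g. CV test
#' folds): training-set permutation importance is biased towards overfit
#' features. Importances may be negative; they do not sum to any fixed
#' total.
#'
#' @param classifier A fitted classifier (e.g. [train_svm()] result).
#' @param X Held-out feature matrix.
#' @param y Held-out labels.
#' @param metric Scoring metric; `"accuracy"` only.
#' @param repeats Number of seeded shuffles per feature (>= 1).
#' @param seed Seed for the shuffles.
#' @return An object of class `importance_table`: `data.frame` with
#'   `feature`, `provenance`, `importance` (mean over repeats), `sd`,
#'   `rank` (1 = most important; ties broken by feature name), plus
#'   attributes `baseline` and `repeats`.
#' @export
permutation_importance <- function(classifier, X, y,
                                   metric = "accuracy", repeats = 10L,
                                   seed = 1L) {
  metric <- match.arg(metric, "accuracy")
  if (repeats < 1L) stop("repeats must be >= 1")
  if (is.null(classifier)) stop("state error: classifier is not fitted")
  prov <- attr(X, "provenance")
  X <- unclass_matrix(X)
  if (is.null(prov)) prov <- rep(NA_character_, ncol(X))
  y <- as.character(y)
  nm <- colnames(X)
  if (is.null(nm)) nm <- sprintf("f%02d", seq_len(ncol(X)))
  score <- function(Xe) mean(predict_any(classifier, Xe)$class == y)
  baseline <- score(X)
  withr::with_seed(as.integer(seed), {
    imp <- matrix(NA_real_, repeats, ncol(X))
    for (r in seq_len(repeats)) {
      for (j in seq_len(ncol(X))) {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        imp[r, j] <- baseline - score(Xp)
      }
    }
  })
  means <- colMeans(imp)
  sds <- apply(imp, 2L, stats::sd)
  ord <- order(-means, nm)
  rank <- integer(ncol(X)); rank[ord] <- seq_len(ncol(X))
  out <- data.frame(feature = nm, provenance = prov, importance = means,
                    sd = sds, rank = rank, stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  attr(out, "repeats") <- repeats
  class(out) <- c("importance_table", class(out))
  out
}

#' Top-ranked features from an importance table
#'
#' Descending by mean importance, ties broken lexicographically by feature
#' name for determinism; `top_k` larger than the table returns the full
#' ranking.
#'
#' @param table An `importance_table`.
#' @param top_k Number of features to return (> 0).
#' @return The top rows of the table, in rank order.
#' @export
rank_features <- function(table, top_k = nrow(table)) {
  if (nrow(table) == 0L) stop("importance table is empty")
  if (top_k <= 0) stop("parameter error: top_k must be > 0")
  tab <- table[order(table$rank), , drop = FALSE]
  utils::head(tab, min(top_k, nrow(tab)))
}

#' @export
print.importance_table <- function(x, ...) {
  cat("<importance_table> baseline accuracy",
      sprintf("%.4f", attr(x, "baseline")), "-", attr(x, "repeats"),
      "shuffle repeats\n")
  print.data.frame(utils::head(x[order(x$rank), ], 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more features\n")
  invisible(x)
}

#' @export
plot.importance_table <- function(x, top_k = 15L, ...) {
  tab <- rank_features(x, top_k)
  tab <- tab[rev(seq_len(nrow(tab))), ]
  graphics::barplot(tab$importance, names.arg = tab$feature, horiz = TRUE,
                    las = 1, col = ifelse(tab$provenance == "stat",
                                          "tan2", "steelblue"),
                    xlab = "permutation importance (accuracy drop)", ...)
  invisible(x)
}
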