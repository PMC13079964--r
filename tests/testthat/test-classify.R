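test_that("linear SVM separates a separable toy problem", {
  X <- rbind(cbind(runif(20, 0, 1), runif(20, 0, 1)),
             cbind(runif(20, 5, 6), runif(20, 5, 6)))
  y <- rep(c("lo", "hi"), each = 20)
  m <- train_svm(X, y, C = 0.1)
  expect_equal(mean(predict(m, X) == y), 1.0)
  expect_error(train_svm(X, y, C = 0), "C must be")
  expect_error(train_svm(X, rep("lo", 40)), "2 classes")
})

test_that("conflicting duplicate rows cap training accuracy at one half", {
  X <- matrix(rep(c(1, 2), each = 10), 20, 1)
  y <- rep(c("a", "b"), 10)           # same x, alternating labels
  m <- train_svm(X, y, C = 0.1)
  expect_lte(mean(predict(m, X) == y), 0.5)
})

test_that("metrics match hand-computed values on a fixed confusion matrix", {
  truth <- c(rep("a", 10), rep("b", 8), rep("c", 6))
  pred <- c(rep("a", 8), "b", "c",              # row a: 8 1 1
            "a", "a", rep("b", 6),              # row b: 2 6 0
            "b", "b", rep("c", 4))              # row c: 0 2 4
  m <- compute_metrics(truth, pred)
  expect_equal(m$accuracy, 18 / 24)
  expect_equal(as.vector(m$confusion),
               c(8, 2, 0, 1, 6, 2, 1, 0, 4))
  expect_equal(m$per_class$precision, c(8 / 10, 6 / 9, 4 / 5))
  expect_equal(m$per_class$recall, c(8 / 10, 6 / 8, 4 / 6))
  expect_equal(m$per_class$f1, c(0.8, 12 / 17, 8 / 11))
  expect_equal(unname(m$macro["precision"]), (8 / 10 + 6 / 9 + 4 / 5) / 3)
  expect_equal(unname(m$macro["recall"]), (8 / 10 + 6 / 8 + 4 / 6) / 3)
  expect_equal(unname(m$macro["f1"]), (0.8 + 12 / 17 + 8 / 11) / 3)
  expect_equal(unname(m$weighted["precision"]),
               (10 * 8 / 10 + 8 * 6 / 9 + 6 * 4 / 5) / 24)
  expect_equal(unname(m$weighted["recall"]), 18 / 24)
  expect_equal(unname(m$weighted["f1"]),
               (10 * 0.8 + 8 * 12 / 17 + 6 * 8 / 11) / 24)
})

test_that("one-vs-rest AUC matches hand-computed values on a fixed score table", {
  truth <- c("a", "a", "b", "b", "c", "c")
  pred <- truth                               # prediction irrelevant for AUC
  scores <- cbind(a = c(0.9, 0.4, 0.5, 0.2, 0.3, 0.1),
                  b = c(0.1, 0.3, 0.8, 0.6, 0.5, 0.2),
                  c = c(0.0, 0.3, 0.1, 0.2, 0.7, 0.4))
  m <- compute_metrics(truth, pred, scores)
  # class a: positive scores {0.9, 0.4} vs {0.5, 0.2, 0.3, 0.1}:
  # 0.9 beats 4, 0.4 beats 3 -> 7/8
  expect_equal(unname(m$auc_per_class["a"]), 7 / 8)
  # class b: {0.8, 0.6} vs {0.1, 0.3, 0.5, 0.2}: all 8 pairs won
  expect_equal(unname(m$auc_per_class["b"]), 1)
  # class c: {0.7, 0.4} vs {0.0, 0.3, 0.1, 0.2}: all 8 pairs won
  expect_equal(unname(m$auc_per_class["c"]), 1)
  expect_equal(m$auc_macro, (7 / 8 + 1 + 1) / 3)
})

test_that("AUC is invariant to monotone transformation of scores", {
  withr::with_seed(6, {
    truth <- sample(c("a", "b"), 40, replace = TRUE)
    s <- rnorm(40) + (truth == "a")
  })
  scores1 <- cbind(a = s, b = -s)
  scores2 <- cbind(a = exp(s), b = -exp(s))
  m1 <- compute_metrics(truth, truth, scores1)
  m2 <- compute_metrics(truth, truth, scores2)
  expect_equal(m1$auc_per_class, m2$auc_per_class)
})

test_that("fold assignment is stratified, grouped and seed-stable", {
  withr::with_seed(1, {
    y <- rep(c("a", "b", "c"), each = 20)
    fa <- sleepmos:::make_folds(y, NULL, 5, seed = 2)
    # class proportions preserved within +-1 per fold
    for (f in 1:5) {
      tb <- table(factor(y[fa$fold == f], c("a", "b", "c")))
      expect_true(all(abs(tb - 4) <= 1))
    }
    fb <- sleepmos:::make_folds(y, NULL, 5, seed = 2)
    expect_identical(fa$fold, fb$fold)
    # grouping keeps all rows of one group in one fold
    grp <- rep(sprintf("g%02d", 1:12), each = 5)
    yg <- rep(rep(c("a", "b", "c"), each = 4)[1:12], each = 5)
    fg <- sleepmos:::make_folds(yg, grp, 4, seed = 3)
    expect_true(all(tapply(fg$fold, grp, function(v) length(unique(v))) == 1))
    expect_warning(sleepmos:::make_folds(yg, grp, 10, seed = 3), "reduced")
  })
})

test_that("cross-validation detects leaked labels and is reproducible", {
  withr::with_seed(4, {
    y <- rep(c("a", "b", "c"), each = 15)
    # indicator (one-hot) leak columns keep every class linearly separable
    X <- cbind(as.numeric(y == "a"), as.numeric(y == "b"),
               as.numeric(y == "c"), matrix(rnorm(45 * 3), 45, 3))
  })
  r1 <- cross_validate(X, y, folds = 5, seed = 7)
  expect_equal(r1$accuracy, 1.0)
  expect_equal(r1$auc_macro, 1.0)
  r2 <- cross_validate(X, y, folds = 5, seed = 7)
  expect_identical(r1$window_pred, r2$window_pred)
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("participant-level vote breaks ties towards the worst class", {
  pred <- c("0", "2", "0", "2", "1")
  y <- rep("0", 5)
  grp <- rep("p1", 5)
  # 2-2-1 tie between "0" and "2": conservative vote picks "2"
  agg <- sleepmos:::participant_vote(pred, y, grp, c("0", "1", "2"))
  expect_equal(agg$pred, "2")
})

test_that("tree baselines run on the same fused features", {
  d <- planted_feature_design(n = 90, p = 6, informative = 1:2,
                              effect = 2, classes = 3, seed = 8)
  rf <- cross_validate(d$X, d$y, folds = 3, seed = 1,
                       classifier = "random_forest")
  gb <- cross_validate(d$X, d$y, folds = 3, seed = 1,
                       classifier = "gradient_boosting")
  expect_gt(rf$accuracy, 1 / 3)
  expect_gt(gb$accuracy, 1 / 3)
})
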