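test_that("backpropagation matches numerical gradients on a tiny network", {
  withr::with_seed(3, {
    sizes <- c(4L, 3L)
    X <- matrix(rnorm(5 * 6), 5, 6)
    Y <- diag(2)[sample(1:2, 5, replace = TRUE), , drop = FALSE]
    params <- sleepmos:::init_lstm_params(sizes, 2L)
  })
  fw <- sleepmos:::lstm_forward(params, X, sizes, keep_cache = TRUE)
  bw <- sleepmos:::lstm_backward(params, fw, X, Y, sizes)
  num_grad <- function(get, set) {
    w <- get(params); g <- w * 0
    for (i in seq_along(w)) {
      for (s in c(1, -1)) {
        p2 <- set(params, `[<-`(w, i, w[i] + s * 1e-5))
        f2 <- sleepmos:::lstm_forward(p2, X, sizes, keep_cache = TRUE)
        g[i] <- g[i] + s * sleepmos:::lstm_backward(p2, f2, X, Y, sizes)$loss / 2e-5
      }
    }
    g
  }
  for (l in 1:2) for (k in c("Wx", "Wh", "b")) {
    ng <- num_grad(function(p) p$layers[[l]][[k]],
                   function(p, w) { p$layers[[l]][[k]][] <- w; p })
    expect_lt(max(abs(ng - bw$grads$layers[[l]][[k]])), 1e-7)
  }
  ng <- num_grad(function(p) p$Wy, function(p, w) { p$Wy[] <- w; p })
  expect_lt(max(abs(ng - bw$grads$Wy)), 1e-7)
})

test_that("extractor output dimension equals the last layer size", {
  withr::with_seed(8, {
    X <- matrix(runif(60 * 24), 60, 24)
    y <- rep(c("a", "b"), 30)
  })
  cfg <- fast_lstm_config()
  ex <- train_extractor(X, y, layer_sizes = c(10L, 6L), config = cfg)
  f <- extract_deep_features(ex, X)
  expect_equal(dim(f), c(60, 6))
  expect_equal(colnames(f)[1], "deep01")
})

test_that("inference is deterministic and training is seed-reproducible", {
  withr::with_seed(8, {
    X <- matrix(runif(40 * 24), 40, 24)
    y <- rep(c("a", "b"), 20)
  })
  cfg <- fast_lstm_config()
  ex1 <- train_extractor(X, y, layer_sizes = c(8L, 5L), config = cfg)
  ex2 <- train_extractor(X, y, layer_sizes = c(8L, 5L), config = cfg)
  expect_identical(extract_deep_features(ex1, X), extract_deep_features(ex2, X))
  # same window twice -> identical rows
  f <- extract_deep_features(ex1, rbind(X[1, ], X[1, ]))
  expect_identical(f[1, ], f[2, ])
})

test_that("invalid training inputs raise parameter errors", {
  X <- matrix(runif(10 * 24), 10, 24)
  expect_error(train_extractor(X, rep("a", 10)), "single class")
  cfg <- sleepmos_config(); cfg$extractor$dropout <- 1.0
  expect_error(train_extractor(X, rep(c("a", "b"), 5), config = cfg),
               "dropout")
  ex <- train_extractor(X, rep(c("a", "b"), 5),
                        layer_sizes = c(6L, 4L), config = fast_lstm_config())
  expect_error(extract_deep_features(ex, X[, 1:23]), "shape error")
  expect_error(extract_deep_features(structure(list(trained = FALSE),
                                               class = "lstm_extractor"), X),
               "state error")
})

test_that("the softmax head learns a separable sequence problem", {
  # class decided by the mean level of the sequence
  withr::with_seed(5, {
    n <- 80
    y <- rep(c("lo", "hi"), n / 2)
    X <- matrix(runif(n * 24, 0, 0.2), n, 24) +
      ifelse(y == "hi", 0.7, 0)
  })
  cfg <- sleepmos_config()
  cfg$extractor$epochs <- 40L; cfg$extractor$patience <- 40L
  ex <- train_extractor(X, y, layer_sizes = c(8L, 6L), config = cfg)
  pred <- predict_lstm_head(ex, X)$class
  expect_gte(mean(pred == y), 0.95)
  # deep features alone separate the classes linearly
  f <- extract_deep_features(ex, X)
  m <- train_svm(f, y, C = 0.1)
  expect_gte(mean(predict(m, f) == y), 0.95)
})
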