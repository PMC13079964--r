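small_cfg <- function(seed = 1L) {
  cfg <- small_search_config()
  cfg$genetic$seed <- seed
  cfg$pso$seed <- seed
  cfg
}

test_that("subset fitness rewards perfect predictors and penalises empties", {
  withr::with_seed(2, {
    y <- rep(c("a", "b"), 30)
    X <- cbind(leak = as.numeric(y == "a"), noise = rnorm(60))
  })
  expect_equal(evaluate_subset_fitness(c(TRUE, FALSE), X, y), 1.0)
  expect_equal(evaluate_subset_fitness(c(FALSE, FALSE), X, y), 0)
  expect_error(evaluate_subset_fitness(c(TRUE, TRUE, TRUE), X, y), "length")
  f1 <- evaluate_subset_fitness(c(TRUE, TRUE), X, y, seed = 9)
  f2 <- evaluate_subset_fitness(c(TRUE, TRUE), X, y, seed = 9)
  expect_identical(f1, f2)
})

test_that("pure-noise features give near-chance fitness", {
  withr::with_seed(11, {
    vals <- replicate(30, {
      y <- rep(c("a", "b"), 40)
      X <- matrix(rnorm(80 * 4), 80, 4)
      evaluate_subset_fitness(rep(TRUE, 4), X, y,
                              seed = sample.int(1000, 1))
    })
  })
  expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("genetic search recovers planted features and is deterministic", {
  d <- planted_feature_design(n = 200, p = 10, informative = 1:2,
                              effect = 1.5, seed = 3)
  cfg <- small_cfg(3)
  g1 <- genetic_search(d$X, d$y, cfg)
  expect_true(all(g1$mask[1:2]))
  g2 <- genetic_search(d$X, d$y, cfg)
  expect_identical(g1$mask, g2$mask)
  # evaluation budget respected
  expect_lte(g1$n_evaluations,
             cfg$genetic$population * (cfg$genetic$generations + 1L))
  # best-ever fitness is non-decreasing over generations
  expect_true(all(diff(g1$log$best) >= 0))
})

test_that("degenerate genetic limits return the evaluated initial individual", {
  d <- planted_feature_design(n = 60, p = 5, informative = 1, seed = 2)
  cfg <- small_cfg(2)
  cfg$genetic$population <- 1L
  cfg$genetic$generations <- 0L
  g <- genetic_search(d$X, d$y, cfg)
  expect_equal(sum(!is.na(g$fitness)), 1)
  expect_true(any(g$mask))
  expect_equal(nrow(g$log), 1)
})

test_that("geometric PSO recovers planted features and is deterministic", {
  d <- planted_feature_design(n = 200, p = 10, informative = 1:2,
                              effect = 1.5, seed = 4)
  cfg <- small_cfg(4)
  p1 <- pso_search(d$X, d$y, cfg)
  expect_true(all(p1$mask[1:2]))
  expect_identical(p1$mask, pso_search(d$X, d$y, cfg)$mask)
  expect_true(all(diff(p1$log$best) >= 0))
})

test_that("a frozen swarm never moves", {
  d <- planted_feature_design(n = 80, p = 6, informative = 1, seed = 5)
  cfg <- small_cfg(5)
  cfg$pso$inertia_weight <- 1
  cfg$pso$individual_weight <- 0
  cfg$pso$social_weight <- 0
  cfg$pso$mutation_prob <- 0
  frozen <- pso_search(d$X, d$y, cfg)
  # best equals the best initial particle: iteration log never improves
  expect_equal(frozen$log$best, rep(frozen$log$best[1], nrow(frozen$log)))
})

test_that("PSO weight validation rejects non-normalised weights", {
  d <- planted_feature_design(n = 40, p = 4, seed = 1)
  cfg <- small_cfg(1)
  cfg$pso$inertia_weight <- 0.5
  expect_error(pso_search(d$X, d$y, cfg), "sum to 1")
})

test_that("subset union is bitwise OR with set semantics", {
  a <- sleepmos:::new_feature_subset(c(TRUE, FALSE, TRUE, FALSE), 0.8, "genetic")
  b <- sleepmos:::new_feature_subset(c(FALSE, FALSE, TRUE, TRUE), 0.7, "pso")
  u <- subset_union(a, b)
  expect_equal(which(u$mask), c(1, 3, 4))
  expect_equal(u$provenance, "union")
  expect_equal(which(subset_union(a, a)$mask), which(a$mask))      # idempotent
  empty <- sleepmos:::new_feature_subset(rep(FALSE, 4), 0, "pso")
  expect_equal(which(subset_union(a, empty)$mask), which(a$mask))  # identity
  expect_gte(sum(u$mask), max(sum(a$mask), sum(b$mask)))
  short <- sleepmos:::new_feature_subset(c(TRUE, TRUE), 0.5, "pso")
  expect_error(subset_union(a, short), "index space")
})
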