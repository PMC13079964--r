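new_feature_subset <- function(mask, fitness, provenance, log = NULL,
                               n_evaluations = NA_integer_) {
  structure(list(mask = as.logical(mask), fitness = fitness,
                 provenance = provenance, log = log,
                 n_evaluations = n_evaluations),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("<feature_subset> %s: %d/%d features selected, fitness %s\n",
              x$provenance, sum(x$mask), length(x$mask),
              ifelse(is.na(x$fitness), "NA", sprintf("%.4f", x$fitness))))
  if (sum(x$mask) > 0)
    cat("  indices:", paste(which(x$mask), collapse = ", "), "\n")
  invisible(x)
}

#' Wrapper fitness of a feature subset
#'
#' Fitness is the mean stratified cross-validated accuracy of the stated
#' classifier restricted to the masked columns. The empty mask scores 0 (a
#' penalty, not an error). Deterministic for fixed seed.
#'
#' @param mask Logical (or 0/1) vector over feature columns.
#' @param X Feature matrix.
#' @param y Labels.
#' @param classifier `"svm"` (linear) or `"logistic"`.
#' @param cv_folds Internal CV folds (default 5).
#' @param seed Fold-assignment seed.
#' @param C SVM regularisation parameter.
#' @param fold Optional precomputed fold assignment (integer id per row);
#'   computed from `cv_folds` and `seed` when `NULL`.
#' @return Fitness in [0, 1].
#' @export
evaluate_subset_fitness <- function(mask, X, y, classifier = "svm",
                                    cv_folds = 5L, seed = 1L, C = 0.1,
                                    fold = NULL) {
  mask <- as.logical(mask)
  if (length(mask) != ncol(X)) stop("mask length must equal feature count")
  if (!any(mask)) return(0)
  Xm <- unclass_matrix(X)[, mask, drop = FALSE]
  y <- as.character(y)
  if (is.null(fold)) {
    fa <- make_folds(y, NULL, cv_folds, seed)
    fold <- fa$fold
  }
  accs <- vapply(seq_len(max(fold)), function(f) {
    tr <- fold != f
    model <- fit_wrapper_classifier(Xm[tr, , drop = FALSE], y[tr],
                                    classifier, C = C)
    mean(predict(model, Xm[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(accs)
}

# memoised fitness within one search run; the (mask-independent) fold
# assignment is computed once
make_fitness_fn <- function(X, y, classifier, cv_folds, seed, C) {
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  fold <- make_folds(as.character(y), NULL, cv_folds, seed)$fold
  list(
    fit = function(mask) {
      key <- paste(as.integer(mask), collapse = "")
      if (!is.null(cache[[key]])) return(cache[[key]])
      n_evals <<- n_evals + 1L
      val <- evaluate_subset_fitness(mask, X, y, classifier, cv_folds, seed,
                                     C, fold = fold)
      cache[[key]] <- val
      val
    },
    evals = function() n_evals
  )
}

# strictly-better-or-equal-with-parsimony comparison
better_subset <- function(f_new, size_new, f_best, size_best) {
  f_new > f_best || (f_new == f_best && size_new < size_best)
}

random_mask <- function(n) {
  m <- stats::rbinom(n, 1L, 0.5) == 1L
  if (!any(m)) m[sample.int(n, 1L)] <- TRUE
  m
}

#' Genetic wrapper feature selection
#'
#' Classic binary genetic algorithm over feature masks: random
#' initialisation, fitness by cross-validated classifier accuracy
#' ([evaluate_subset_fitness()], linear SVM by default), tournament
#' selection (size 2), single-point crossover (probability 0.6), per-bit
#' flip mutation (probability 0.033), elitism of one, for 20 generations of
#' a population of 20. Fitness ties break towards the smaller subset. The
#' best-ever subset is returned with a per-generation log of best and mean
#' fitness.
#'
#' @param X Feature matrix (the deep-feature block).
#' @param y Labels.
#' @param config Configuration list; uses the `genetic` block and `svm$C`.
#' @return A `feature_subset` with provenance `"genetic"`.
#' @export
genetic_search <- function(X, y, config = sleepmos_config()) {
  g <- config$genetic
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 features to search over")
  withr::with_seed(as.integer(g$seed), {
    fx <- make_fitness_fn(X, y, g$fitness_classifier, g$cv_folds, g$seed,
                         config$svm$C)
    pop <- t(vapply(seq_len(g$population), function(i) random_mask(n),
                    logical(n)))
    fit <- apply(pop, 1L, fx$fit)
    best_mask <- pop[which.max(fit), ]; best_fit <- max(fit)
    log <- data.frame(generation = 0L, best = best_fit, mean = mean(fit))
    tournament <- function() {
      ij <- sample.int(g$population, 2L, replace = TRUE)
      a <- ij[1]; b <- ij[2]
      if (better_subset(fit[a], sum(pop[a, ]), fit[b], sum(pop[b, ]))) a else b
    }
    if (g$generations >= 1L) for (gen in seq_len(g$generations)) {
      elite <- pop[which.max(fit), , drop = FALSE]
      newpop <- elite
      while (nrow(newpop) < g$population) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        if (stats::runif(1) < g$crossover_prob && n >= 2L) {
          cut <- sample.int(n - 1L, 1L)
          c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):n])
          c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):n])
        } else { c1 <- p1; c2 <- p2 }
        for (child in list(c1, c2)) {
          flip <- stats::runif(n) < g$mutation_prob
          child <- xor(child, flip)
          if (!any(child)) child[sample.int(n, 1L)] <- TRUE
          if (nrow(newpop) < g$population) newpop <- rbind(newpop, child)
        }
      }
      pop <- newpop
      fit <- apply(pop, 1L, fx$fit)
      gi <- which.max(fit)
      if (better_subset(fit[gi], sum(pop[gi, ]), best_fit, sum(best_mask))) {
        best_fit <- fit[gi]; best_mask <- pop[gi, ]
      }
      log <- rbind(log, data.frame(generation = gen, best = best_fit,
                                   mean = mean(fit)))
    }
    new_feature_subset(best_mask, best_fit, "genetic", log, fx$evals())
  })
}

#' Geometric (velocity-free) binary PSO feature selection
#'
#' Discrete particle swarm variant without a velocity term: each particle's
#' next position is a three-parent geometric recombination of its current
#' position, its personal best, and the swarm's global best - every bit is
#' copied from one of the three parents with probabilities equal to the
#' inertia, individual and social weights (0.33 / 0.34 / 0.33) - followed by
#' per-bit mutation (default probability 1 / n_features). Fitness is
#' cross-validated accuracy of a logistic-regression wrapper by default.
#' Runs 20 iterations of 20 particles and returns the global best; ties
#' break towards the smaller subset.
#'
#' @param X Feature matrix (the deep-feature block).
#' @param y Labels.
#' @param config Configuration list; uses the `pso` block and `svm$C`.
#' @return A `feature_subset` with provenance `"pso"`.
#' @export
pso_search <- function(X, y, config = sleepmos_config()) {
  p <- config$pso
  w3 <- c(p$inertia_weight, p$individual_weight, p$social_weight)
  if (abs(sum(w3) - 1) > 1e-8)
    stop("config error: PSO weights must sum to 1")
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 features to search over")
  pmut <- if (is.na(p$mutation_prob)) 1 / n else p$mutation_prob
  withr::with_seed(as.integer(p$seed), {
    fx <- make_fitness_fn(X, y, p$fitness_classifier, p$cv_folds, p$seed,
                         config$svm$C)
    pos <- t(vapply(seq_len(p$population), function(i) random_mask(n),
                    logical(n)))
    fit <- apply(pos, 1L, fx$fit)
    pbest <- pos; pbest_fit <- fit
    gi <- which.max(pbest_fit)
    gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]
    log <- data.frame(iteration = 0L, best = gbest_fit, mean = mean(fit))
    if (p$iterations >= 1L) for (it in seq_len(p$iterations)) {
      for (i in seq_len(p$population)) {
        src <- sample.int(3L, n, replace = TRUE, prob = w3)
        newpos <- ifelse(src == 1L, pos[i, ],
                         ifelse(src == 2L, pbest[i, ], gbest))
        flip <- stats::runif(n) < pmut
        newpos <- xor(as.logical(newpos), flip)
        pos[i, ] <- newpos
        f <- fx$fit(newpos)
        fit[i] <- f
        if (better_subset(f, sum(newpos), pbest_fit[i], sum(pbest[i, ]))) {
          pbest[i, ] <- newpos; pbest_fit[i] <- f
        }
        if (better_subset(f, sum(newpos), gbest_fit, sum(gbest))) {
          gbest <- newpos; gbest_fit <- f
        }
      }
      log <- rbind(log, data.frame(iteration = it, best = gbest_fit,
                                   mean = mean(fit)))
    }
    new_feature_subset(gbest, gbest_fit, "pso", log, fx$evals())
  })
}

#' Union of two selected feature subsets
#'
#' Bitwise OR over the two masks (which must cover the same feature index
#' space): a feature chosen by either search is kept. The union's fitness
#' is not inherited (re-evaluate if needed).
#'
#' @param a,b `feature_subset` objects of equal mask length.
#' @return A `feature_subset` with provenance `"union"`.
#' @export
subset_union <- function(a, b) {
  stopifnot(inherits(a, "feature_subset"), inherits(b, "feature_subset"))
  if (length(a$mask) != length(b$mask))
    stop("parameter error: masks cover different feature index spaces")
  new_feature_subset(a$mask | b$mask, NA_real_, "union")
}

#' Planted-signal feature matrix for validating wrapper selection
#'
#' Generates a labelled feature matrix in which a known subset of columns
#' carries class signal (class-dependent mean shift) and the rest are pure
#' noise - the standard planted design for checking that wrapper selection
#' recovers informative features.
#'
#' @param n Number of rows (windows).
#' @param p Number of features.
#' @param informative Indices of informative columns.
#' @param classes Number of balanced classes.
#' @param effect Mean shift per class step on informative columns.
#' @param seed Seed.
#' @return List with `X` (n x p matrix), `y` (labels), `informative`.
#' @export
planted_feature_design <- function(n = 400L, p = 15L, informative = 1:3,
                                   classes = 2L, effect = 1.0, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    y <- rep(seq_len(classes) - 1L, length.out = n)
    X <- matrix(stats::rnorm(n * p), n, p)
    for (j in informative) X[, j] <- X[, j] + effect * y
    colnames(X) <- sprintf("f%02d", seq_len(p))
    list(X = X, y = as.character(y), informative = informative)
  })
}
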