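#' Genetic-algorithm configuration for (C, g) search
#'
#' Real-coded GA over the two SVM hyperparameters.  Fitness is the K-fold
#' cross-validated accuracy (maximized directly in the roulette weights);
#' selection is fitness-proportional, crossover is the arithmetic blend
#' `a_k' = a_k (1 - b) + a_l b` with `b ~ U(0, 1)` per gene, and mutation is
#' the non-uniform boundary-decaying move toward a bound with decay
#' `f(g) = r2 (1 - g / Gmax)^2`.  One elite individual is carried over each
#' generation, making the best-fitness trace non-decreasing.
#'
#' @param pop_size Population size N (>= 2).
#' @param generations Maximum generations Gmax (>= 1).
#' @param cv_folds K for the cross-validation fitness.
#' @param c_bounds,g_bounds Search intervals for C and g (positive,
#'   min < max).
#' @param crossover_rate,mutation_rate Per-pair and per-gene operator
#'   probabilities.
#' @param rng_seed Integer seed; the whole search is deterministic given it.
#' @return A `ga_config` object.
#' @export
ga_config <- function(pop_size = 20, generations = 200, cv_folds = 10,
                      c_bounds = c(0.01, 100), g_bounds = c(0.01, 100),
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      rng_seed = 1L) {
  stopifnot(pop_size >= 2, generations >= 1, cv_folds >= 2,
            length(c_bounds) == 2, c_bounds[1] > 0, diff(c_bounds) > 0,
            length(g_bounds) == 2, g_bounds[1] > 0, diff(g_bounds) > 0,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(pop_size = pop_size, generations = generations,
                 cv_folds = cv_folds, c_bounds = c_bounds,
                 g_bounds = g_bounds, crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

# Non-uniform mutation: move toward the upper bound when r > 0.5, else
# toward the lower bound, by a fraction f = r2 (1 - g/Gmax)^2 of the
# remaining distance.  Always stays inside [amin, amax].
ga_mutate_gene <- function(a, amin, amax, gen, gmax) {
  r <- runif(1)
  f <- runif(1) * (1 - gen / gmax)^2
  if (r > 0.5) a + (amax - a) * f else a + (amin - a) * f
}

#' GA search for the best (C, g) of an RBF SVM
#'
#' @param X Feature matrix; `y` labels in `{-1, +1}`.
#' @param cfg A [ga_config()].
#' @return List with `C`, `g`, `fitness` (best CV accuracy), `trace`
#'   (best fitness per generation, non-decreasing), and `population`
#'   (final genes).
#' @export
ga_optimize <- function(X, y, cfg = ga_config()) {
  X <- as.matrix(X)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  set.seed(cfg$rng_seed)
  cv_seed <- derive_seed(cfg$rng_seed, "cvfolds")  # same folds for all
  K <- min(cfg$cv_folds, min(table(y)), nrow(X))
  if (K < 2) stop("too few samples per class for cross-validation")
  evaluate <- function(genes)
    apply(genes, 1, function(p)
      kfold_cv_accuracy(X, y, svm_spec(p[1], p[2]), K = K, seed = cv_seed))

  N <- cfg$pop_size
  # both hyperparameters span several decades: seed the population
  # log-uniformly so small kernel widths are represented; the genetic
  # operators themselves act on the linear scale
  genes <- cbind(10^runif(N, log10(cfg$c_bounds[1]), log10(cfg$c_bounds[2])),
                 10^runif(N, log10(cfg$g_bounds[1]), log10(cfg$g_bounds[2])))
  fit <- evaluate(genes)
  best_i <- which.max(fit)
  best <- list(genes = genes[best_i, ], fitness = fit[best_i])
  trace <- numeric(cfg$generations)

  lo <- c(cfg$c_bounds[1], cfg$g_bounds[1])
  hi <- c(cfg$c_bounds[2], cfg$g_bounds[2])
  for (gen in seq_len(cfg$generations)) {
    # roulette selection, probability proportional to fitness
    w <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / N, N)
    parents <- genes[sample.int(N, N, replace = TRUE, prob = w), ,
                     drop = FALSE]
    # arithmetic crossover on consecutive pairs
    for (p in seq(1, N - 1, by = 2)) {
      if (runif(1) < cfg$crossover_rate) {
        for (j in 1:2) {
          b <- runif(1)
          ak <- parents[p, j]; al <- parents[p + 1, j]
          parents[p, j]     <- ak * (1 - b) + al * b
          parents[p + 1, j] <- al * (1 - b) + ak * b
        }
      }
    }
    # boundary-decaying mutation
    for (i in seq_len(N))
      for (j in 1:2)
        if (runif(1) < cfg$mutation_rate)
          parents[i, j] <- ga_mutate_gene(parents[i, j], lo[j], hi[j],
                                          gen, cfg$generations)
    # elitism: the incumbent best replaces the first slot
    parents[1, ] <- best$genes
    genes <- parents
    fit <- evaluate(genes)
    gi <- which.max(fit)
    if (fit[gi] > best$fitness)
      best <- list(genes = genes[gi, ], fitness = fit[gi])
    trace[gen] <- best$fitness
  }
  list(C = best$genes[1], g = best$genes[2], fitness = best$fitness,
       trace = trace, population = genes)
}

#' Train the hierarchical two-stage mental-state classifier
#'
#' Stage 1 separates Category II (level 3, the fatigued state) from
#' Category I (levels 1--2); stage 2, trained on Category-I rows only,
#' separates level 1 from level 2.  Each stage's (C, g) is searched by an
#' independent GA run (set `share_params = TRUE` to reuse the stage-1
#' optimum for stage 2).
#'
#' @param features A `feature_table` (or data.frame) containing
#'   `feature_cols` and a `level` column in `{1, 2, 3}`.
#' @param feature_cols Input variable columns; by convention reaction time
#'   plus the top-ranked physiological factor.
#' @param ga A [ga_config()].
#' @param share_params Reuse stage-1 (C, g) for stage 2.
#' @return A `hierarchical_model` with fitted `stage1`, `stage2`, the
#'   per-stage GA results, and `feature_cols`.
#' @export
train_hierarchical <- function(features,
                               feature_cols = c("reaction_time_s",
                                                "alpha_over_beta"),
                               ga = ga_config(),
                               share_params = FALSE) {
  stopifnot(all(c(feature_cols, "level") %in% names(features)))
  lev <- features$level
  if (!all(1:3 %in% lev))
    stop("training data must contain all three levels")
  X <- as.matrix(features[, feature_cols, drop = FALSE])

  y1 <- ifelse(lev == 3, 1, -1)
  ga1 <- ga_optimize(X, y1,
                     cfg = modify_ga_seed(ga, derive_seed(ga$rng_seed,
                                                          "stage1")))
  stage1 <- train_binary_svm(X, y1, svm_spec(ga1$C, ga1$g))

  catI <- lev %in% c(1, 2)
  X2 <- X[catI, , drop = FALSE]
  y2 <- ifelse(lev[catI] == 2, 1, -1)
  if (share_params) {
    ga2 <- ga1
  } else {
    ga2 <- ga_optimize(X2, y2,
                       cfg = modify_ga_seed(ga, derive_seed(ga$rng_seed,
                                                            "stage2")))
  }
  stage2 <- train_binary_svm(X2, y2, svm_spec(ga2$C, ga2$g))

  structure(list(stage1 = stage1, stage2 = stage2,
                 ga_stage1 = ga1[c("C", "g", "fitness", "trace")],
                 ga_stage2 = ga2[c("C", "g", "fitness", "trace")],
                 feature_cols = feature_cols),
            class = "hierarchical_model")
}

modify_ga_seed <- function(ga, seed) {
  ga$rng_seed <- as.integer(seed)
  ga
}

#' @export
predict.hierarchical_model <- function(object, newdata, ...) {
  stopifnot(all(object$feature_cols %in% names(newdata)))
  X <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  out <- integer(nrow(X))
  p1 <- predict(object$stage1, X)
  out[p1 == 1] <- 3L
  if (any(p1 == -1)) {
    p2 <- predict(object$stage2, X[p1 == -1, , drop = FALSE])
    out[p1 == -1] <- ifelse(p2 == 1, 2L, 1L)
  }
  out
}

#' Serialize / restore a hierarchical model as JSON
#'
#' Stores, per stage: training (standardized) inputs, labels, dual
#' coefficients, threshold, (C, g) and standardization statistics — enough
#' to reproduce the decision function exactly.
#'
#' @param model A `hierarchical_model`.
#' @param path JSON file path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "hierarchical_model"))
  pack <- function(s) list(X = unclass(s$X), y = s$y, alpha = s$alpha,
                           b = s$b, C = s$spec$C, g = s$spec$g,
                           center = s$center, scale = s$scale)
  jsonlite::write_json(list(stage1 = pack(model$stage1),
                            stage2 = pack(model$stage2),
                            feature_cols = model$feature_cols),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(s) structure(
    list(X = as.matrix(s$X), y = as.numeric(s$y),
         alpha = as.numeric(s$alpha), b = s$b,
         spec = svm_spec(s$C, s$g), center = as.numeric(s$center),
         scale = as.numeric(s$scale), converged = TRUE),
    class = "binary_svm")
  structure(list(stage1 = unpack(obj$stage1), stage2 = unpack(obj$stage2),
                 feature_cols = obj$feature_cols),
            class = "hierarchical_model")
}
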