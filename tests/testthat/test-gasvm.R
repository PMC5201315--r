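# small deterministic 2-D binary problems used across the SVM tests
blobs <- function(n_per = 20, gap = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = gap), ncol = 2))
  list(X = X, y = rep(c(-1, 1), each = n_per))
}

test_that("separable blobs are fit almost perfectly", {
  b <- blobs()
  m <- train_binary_svm(b$X, b$y, svm_spec(C = 1, g = 1))
  expect_gte(mean(predict(m, b$X) == b$y), 0.99)
})

test_that("the RBF kernel fits XOR at large C", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(-1, -1, 1, 1)
  m <- train_binary_svm(X, y, svm_spec(C = 1e3, g = 2), standardize = FALSE)
  expect_equal(predict(m, X), y)
})

test_that("duplicating every training point leaves the decision unchanged", {
  # exact duplication invariance needs an interior solution (no alpha at
  # the box bound, where doubling a point doubles its available weight)
  b <- blobs(n_per = 15, gap = 4, seed = 4)
  m1 <- train_binary_svm(b$X, b$y, svm_spec(C = 10, g = 0.5))
  expect_lt(max(m1$alpha), 10)
  m2 <- train_binary_svm(rbind(b$X, b$X), c(b$y, b$y), svm_spec(C = 10, g = 0.5))
  grid <- as.matrix(expand.grid(seq(-2, 5, length.out = 7),
                                seq(-2, 5, length.out = 7)))
  expect_equal(predict(m1, grid), predict(m2, grid))
})

test_that("dual constraints hold at solver tolerance", {
  for (seed in 1:3) {
    b <- blobs(n_per = 12, gap = 2, seed = seed)
    spec <- svm_spec(C = 1.5, g = 0.8)
    m <- train_binary_svm(b$X, b$y, spec)
    expect_true(all(m$alpha >= -1e-6 & m$alpha <= spec$C + 1e-6))
    expect_lt(abs(sum(m$alpha * m$y)), 1e-6)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(train_binary_svm(matrix(1:4, 2), c(1, 1)), "single class")
  expect_error(train_binary_svm(matrix(c(1, NA, 3, 4), 2), c(-1, 1)),
               "non-finite")
})

test_that("cross-validation: separable data, null labels, determinism", {
  b <- blobs(n_per = 25, gap = 5, seed = 2)
  expect_equal(kfold_cv_accuracy(b$X, b$y, K = 5, seed = 3L), 1.0)
  # shuffled balanced labels give chance-level accuracy
  set.seed(11)
  accs <- vapply(1:20, function(i) {
    X <- matrix(rnorm(80), ncol = 2)
    y <- sample(rep(c(-1, 1), 20))
    kfold_cv_accuracy(X, y, svm_spec(1, 1), K = 4, seed = i)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
  a1 <- kfold_cv_accuracy(b$X, b$y, K = 5, seed = 7L)
  a2 <- kfold_cv_accuracy(b$X, b$y, K = 5, seed = 7L)
  expect_identical(a1, a2)
  expect_warning(kfold_cv_accuracy(rbind(b$X, c(0, 9)), c(b$y, 9 == 9), K = 30),
                 "unstratified")
})

test_that("GA: monotone trace, bounded mutation, grid-search parity", {
  b <- blobs(n_per = 15, gap = 4, seed = 5)
  cfg <- ga_config(pop_size = 10, generations = 15, cv_folds = 3,
                   rng_seed = 2L)
  res <- ga_optimize(b$X, b$y, cfg)
  expect_true(all(diff(res$trace) >= 0))
  expect_gte(res$C, cfg$c_bounds[1]); expect_lte(res$C, cfg$c_bounds[2])
  expect_gte(res$g, cfg$g_bounds[1]); expect_lte(res$g, cfg$g_bounds[2])
  # coarse 5x5 grid-search oracle on the same folds
  gr <- expand.grid(C = 10^seq(-2, 2), g = 10^seq(-2, 2))
  cv_seed <- drivefatigue:::derive_seed(2L, "cvfolds")
  grid_acc <- max(vapply(seq_len(nrow(gr)), function(i)
    kfold_cv_accuracy(b$X, b$y, svm_spec(gr$C[i], gr$g[i]), K = 3,
                      seed = cv_seed), numeric(1)))
  expect_gte(res$fitness, grid_acc)
  # mutation from a gene sitting on a bound stays inside the bounds
  set.seed(1)
  for (i in 1:200) {
    lo <- 0.01; hi <- 100
    for (a in c(lo, hi, 50)) {
      out <- drivefatigue:::ga_mutate_gene(a, lo, hi, gen = 3, gmax = 10)
      expect_gte(out, lo); expect_lte(out, hi)
    }
  }
})

test_that("GA search is deterministic given its seed", {
  b <- blobs(n_per = 10, gap = 2.5, seed = 6)
  cfg <- ga_config(pop_size = 4, generations = 3, cv_folds = 2, rng_seed = 5L)
  r1 <- ga_optimize(b$X, b$y, cfg)
  r2 <- ga_optimize(b$X, b$y, cfg)
  expect_identical(r1[c("C", "g", "fitness", "trace")],
                   r2[c("C", "g", "fitness", "trace")])
})

test_that("hierarchical training, prediction and batch invariance", {
  tab <- simulate_feature_rows(n_by_level = c(30, 25, 20), seed = 9L)
  ga <- ga_config(pop_size = 4, generations = 3, cv_folds = 3, rng_seed = 1L)
  model <- train_hierarchical(tab, ga = ga)
  expect_s3_class(model, "hierarchical_model")
  pred <- predict(model, tab)
  expect_true(all(pred %in% 1:3))
  expect_gte(mean(pred == tab$level), 0.85)
  # batch vs row-at-a-time
  one_by_one <- vapply(seq_len(12), function(i)
    predict(model, tab[i, , drop = FALSE]), integer(1))
  expect_equal(one_by_one, pred[1:12])
  # missing level rejected
  expect_error(train_hierarchical(tab[tab$level != 2, ], ga = ga),
               "three levels")
})

test_that("a single point per level is reproduced exactly", {
  tab <- data.frame(reaction_time_s = c(1.0, 1.3, 1.8),
                    alpha_over_beta = c(0.5, 1.1, 2.2),
                    level = 1:3)
  tab <- rbind(tab, tab)  # two copies so CV folds exist
  ga <- ga_config(pop_size = 4, generations = 2, cv_folds = 2, rng_seed = 3L)
  model <- train_hierarchical(tab, ga = ga)
  expect_equal(predict(model, tab), rep(1:3, 2))
})

test_that("model JSON round-trip preserves the decision function", {
  tab <- simulate_feature_rows(n_by_level = c(20, 15, 12), seed = 13L)
  ga <- ga_config(pop_size = 4, generations = 2, cv_folds = 3, rng_seed = 2L)
  model <- train_hierarchical(tab, ga = ga)
  p <- withr::local_tempfile(fileext = ".json")
  write_model(model, p)
  model2 <- read_model(p)
  expect_equal(predict(model2, tab), predict(model, tab))
})
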