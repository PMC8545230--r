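test_that("the sigmoid transfer function thresholds at one half", {
  expect_identical(binarize(0.5), 1L)                 # sigmoid exactly 0.5, >= rule
  expect_identical(binarize(0), 0L)                   # sigmoid ~ 0.00669
  expect_equal(1 / (1 + exp(-10 * (0 - 0.5))), 0.00669, tolerance = 1e-3)
  expect_identical(binarize(c(0.49, 0.51)), c(0L, 1L))
  # monotone: raising components never deselects a feature
  set.seed(1)
  x <- runif(20)
  xp <- pmin(1, x + runif(20, 0, 0.3))
  expect_true(all(binarize(x) <= binarize(xp)))
  expect_error(binarize(c(0.1, NA)), "finite")
})

test_that("selection fitness is the stated convex combination", {
  D <- 8
  expect_equal(fs_fitness(0, rep(1, D), 0.99), 0.01, tolerance = 1e-15)
  expect_equal(fs_fitness(1, rep(1, D), 0.99), 1, tolerance = 1e-15)
  expect_equal(fs_fitness(0.2113, rep(c(1, 0), 4), 0.99), 0.214187, tolerance = 1e-12)
  expect_error(fs_fitness(0.5, rep(1, D), 1.2), "\\[0, 1\\]")
  expect_error(fs_fitness(1.5, rep(1, D), 0.99), "\\[0, 1\\]")
  expect_equal(fs_config(h1 = 0.7)$h2, 0.3, tolerance = 1e-15)
})

test_that("subset error is 0 on a separating feature, 1 on an empty mask", {
  data <- tiny_separable_dataset(n = 40, d = 4, seed = 2)
  m <- c(1L, 0L, 0L, 0L)
  expect_identical(subset_error(data, m), 0)
  expect_identical(subset_error(data, rep(0L, 4)), 1.0)
  expect_error(subset_error(data, c(1L, 0L)), "length 4")
})

test_that("subset error hovers near one half under a permutation null", {
  errs <- sapply(1:20, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(60 * 5), 60, 5)
    y <- rep(c("a", "b"), 30)[sample.int(60)]
    data <- feature_dataset(X, y, seed = s)
    subset_error(data, rep(1L, 5))
  })
  expect_gt(mean(errs), 0.35)
  expect_lt(mean(errs), 0.65)
})

test_that("the wrapper objective factors through the mask and memoizes", {
  data <- tiny_separable_dataset(n = 30, d = 5, seed = 3)
  obj <- make_fs_objective(data)
  x1 <- c(0.9, 0.2, 0.1, 0.3, 0.4)
  x2 <- c(0.6, 0.45, 0.05, 0.2, 0.49)   # same mask 10000
  v1 <- obj(x1); v2 <- obj(x2)
  expect_identical(v1, v2)
  expect_true(v1 >= 0 && v1 <= 1)
  cache <- attr(obj, "cache")
  expect_identical(cache$n_calls, 2L)
  expect_identical(cache$n_evals, 1L)   # one distinct mask scored once
})

test_that("exhaustive enumeration finds the planted features and bounds every optimizer", {
  # planted problems: 2 informative + 4 noise features. The global minimizer
  # draws only on the informative columns (with delta = 4 one of them can
  # already separate the classes, so the size penalty may drop the second)
  for (s in 1:10) {
    data <- generate_planted(planted_spec(n_samples = 60, D = 6, k_informative = 2,
                                          delta = 4, seed = s))
    best <- exhaustive_best_subset(data)
    inf <- attr(data, "informative")
    expect_gte(sum(best$mask[inf]), 1)
    expect_true(all(best$mask[-inf] == 0L),
                label = sprintf("no noise feature selected (seed %d)", s))
  }

  data <- generate_planted(planted_spec(n_samples = 60, D = 6, k_informative = 2,
                                        delta = 4, seed = 1))
  best <- exhaustive_best_subset(data)
  expect_equal(best$fitness, fs_fitness(best$err, best$mask, 0.99))
  for (alg in c("assoa", "ga")) {
    p <- switch(alg, assoa = assoa_params(n = 8, t_m = 15), ga = ga_params(n = 8, t_m = 15))
    sel <- select_features(data, alg, p, seed = 5)
    expect_gte(sel$evaluation$fitness, best$fitness - 1e-12)
  }

  wide <- feature_dataset(matrix(rnorm(40 * 21), 40, 21), rep(c("a", "b"), 20))
  expect_error(exhaustive_best_subset(wide), "D <= 20")
})

test_that("a single feature is selected only when it beats the empty-mask policy", {
  data <- tiny_separable_dataset(n = 30, d = 4, seed = 4)
  one <- feature_dataset(data$X[, 1, drop = FALSE], data$y, seed = 4)
  best <- exhaustive_best_subset(one)
  expect_identical(best$mask, c(1L))
  expect_lt(best$fitness, fs_fitness(1.0, integer(1), 0.99))
})

test_that("selection masks round-trip through CSV", {
  data <- tiny_separable_dataset(n = 20, d = 3, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mask_csv(data, c(1, 0, 1), path)
  df <- utils::read.csv(path)
  expect_identical(df$selected, c(1L, 0L, 1L))
  expect_identical(df$feature_name, data$feature_names)
})
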