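test_that("classification metrics use the standard definitions with null markers", {
  m <- classification_metrics(confusion_counts(50, 40, 5, 5))
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$precision, 50 / 55)
  expect_equal(m$recall, 50 / 55)
  expect_equal(m$specificity, 40 / 45)
  expect_equal(m$f_score, 2 * (50/55)^2 / (2 * 50/55))

  expect_equal(classification_metrics(confusion_counts(10, 5, 0, 2))$precision, 1)
  # no positive predictions at all: precision undefined, never NaN
  m0 <- classification_metrics(confusion_counts(0, 10, 0, 3))
  expect_true(is.na(m0$precision))
  expect_false(is.nan(m0$precision))
  expect_error(confusion_counts(0, 0, 0, 0), "positive")
})

test_that("confusion counts derive correctly from label vectors", {
  truth <- c("p", "p", "n", "n", "p")
  pred <- c("p", "n", "n", "p", "p")
  cc <- confusion_from_predictions(truth, pred, positive = "p")
  expect_identical(unlist(cc[c("TP", "TN", "FP", "FN")]),
                   c(TP = 2L, TN = 1L, FP = 1L, FN = 1L))
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- c(rnorm(30, 1), rnorm(40, 0))
  labels <- rep(c(TRUE, FALSE), c(30, 40))
  ours <- auc_score(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("run statistics summarize fitness with the M-1 denominator", {
  runs <- list(list(fitness = 0.2, error = 0.1, size = 2),
               list(fitness = 0.4, error = 0.3, size = 4))
  st <- fs_run_statistics(runs, D = 8)
  expect_equal(st$mean_fitness, 0.3)
  expect_equal(st$best_fitness, 0.2)
  expect_equal(st$worst_fitness, 0.4)
  expect_equal(st$sd_fitness, sqrt(0.02), tolerance = 1e-12)  # ~0.1414
  expect_equal(st$mean_select_size, 0.375)
  expect_equal(st$mean_error, 0.2)
  identical_runs <- rep(list(list(fitness = 0.3, error = 0.2, size = 3)), 4)
  expect_identical(fs_run_statistics(identical_runs, 8)$sd_fitness, 0)
})

test_that("rank-sum handles the textbook exact cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3, tolerance = 1e-12)
  expect_identical(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  expect_error(wilcoxon_rank_sum(1, c(2, 3)), "at least 2")
})

test_that("exact rank-sum p-values match brute-force enumeration", {
  set.seed(11)
  for (rep in 1:20) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    a <- round(rnorm(m), 2)
    b <- round(rnorm(n, 0.5), 2)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, brute_force_rank_sum_p(a, b),
                 tolerance = 1e-12,
                 label = sprintf("tie-free case m=%d n=%d rep %d", m, n, rep))
  }
  # with ties (integer-valued samples force duplicates)
  for (rep in 1:20) {
    a <- sample(1:4, 4, replace = TRUE)
    b <- sample(1:4, 5, replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, brute_force_rank_sum_p(a, b),
                 tolerance = 1e-12, label = sprintf("tied case rep %d", rep))
  }
})

test_that("rank-sum is invariant under strictly monotone transforms", {
  set.seed(13)
  a <- rexp(6); b <- rexp(7) + 0.2
  base <- wilcoxon_rank_sum(a, b)
  for (f in list(function(x) x^3, log, function(x) 5 * x - 2)) {
    tr <- wilcoxon_rank_sum(f(a), f(b))
    expect_identical(tr$statistic, base$statistic)
    expect_identical(tr$p_value, base$p_value)
  }
})

test_that("large-sample rank-sum agrees with the reference implementation", {
  set.seed(17)
  a <- rnorm(15); b <- rnorm(18, 0.4)
  ours <- wilcoxon_rank_sum(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("two-group ANOVA reduces to the pooled t-test", {
  set.seed(19)
  a <- rnorm(8); b <- rnorm(8, 0.7)
  av <- anova_one_way(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(av$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("ANOVA conserves sums of squares and flags degenerate input", {
  set.seed(23)
  groups <- list(rnorm(6), rnorm(5, 1), rnorm(7, 2))
  av <- anova_one_way(groups)
  expect_equal(av$ss_between + av$ss_within, av$ss_total, tolerance = 1e-9)
  expect_identical(av$df, c(2L, 15L))

  # equal group means with internal spread: F ~ 0
  g <- rnorm(6)
  shifted <- list(g, g - mean(g) + mean(g))  # identical means by construction
  av0 <- anova_one_way(shifted)
  expect_lt(av0$F, 1e-20)

  expect_error(anova_one_way(list(rep(1, 3), rep(1, 4))), "degenerate")
  expect_error(anova_one_way(list(rnorm(3))), "at least 2")
})
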