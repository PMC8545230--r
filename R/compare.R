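#' Multi-run comparison of optimizers on a shared task
#'
#' Runs each algorithm `M` times with paired seeds: run `j` of every
#' algorithm sees the same dataset realization and the same run seed, so
#' differences are attributable to the algorithms alone. Emits per-algorithm
#' summary statistics, pairwise Wilcoxon rank-sum p-values against the
#' reference algorithm, a one-way ANOVA across all algorithms, and the
#' per-run convergence curves.
#'
#' @param task `"fs"` (wrapper feature selection; metric = selection fitness)
#'   or `"mlp"` (optimizer-trained perceptron; metric = test accuracy).
#' @param algorithms Character vector of at least 2 registered algorithm
#'   names; the first is the reference for the pairwise tests.
#' @param M Number of paired runs per algorithm (at least 2).
#' @param seed Base seed; run `j` uses `seed + j`.
#' @param data_generator Function `function(run_seed)` returning the
#'   `feature_dataset` for one run. Defaults: a planted table
#'   (D = 10, 2 informative features) for `"fs"`; a separable task
#'   (n = 200, d = 10, margin 1) for `"mlp"`.
#' @param params Named list of per-algorithm parameter objects (missing or
#'   `NULL` entries use that algorithm's defaults).
#' @param cfg An [fs_config()] (fs task only).
#' @param output_dir Optional directory; when given, the summary, p-values
#'   and curves are written as CSV plus a Markdown summary.
#' @return An object of class `algorithm_comparison`: `summary` (one row per
#'   algorithm), `wilcoxon` (one row per non-reference algorithm), `anova`,
#'   `curves` (long data frame), `metric`, and the per-run metric matrix
#'   `metrics`.
#' @export
compare_algorithms <- function(task = c("fs", "mlp"), algorithms = c("assoa", "ss"),
                               M = 10L, seed = 1L, data_generator = NULL,
                               params = list(), cfg = fs_config(),
                               output_dir = NULL) {
  task <- match.arg(task)
  algorithms <- as.character(algorithms)
  if (length(algorithms) < 2) stop("need at least 2 algorithms to compare", call. = FALSE)
  unknown <- setdiff(algorithms, registered_algorithms())
  if (length(unknown)) {
    stop(sprintf("unknown algorithm(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (M < 2) stop("need at least 2 runs for any statistical test", call. = FALSE)

  if (is.null(data_generator)) {
    data_generator <- if (task == "fs") {
      function(run_seed) generate_planted(planted_spec(
        n_samples = 100, D = 10, k_informative = 2, delta = 3, seed = run_seed))
    } else {
      function(run_seed) generate_separable(200, 10, margin = 1, seed = run_seed)
    }
  }

  metric_name <- if (task == "fs") "fitness" else "test_accuracy"
  metrics <- matrix(NA_real_, M, length(algorithms),
                    dimnames = list(NULL, algorithms))
  runs <- stats::setNames(vector("list", length(algorithms)), algorithms)
  curves <- list()

  for (j in seq_len(M)) {
    run_seed <- as.integer(seed) + j
    data_j <- data_generator(run_seed)
    for (alg in algorithms) {
      pars <- params[[alg]]
      if (task == "fs") {
        sel <- select_features(data_j, alg, pars, cfg, seed = run_seed)
        rec <- list(fitness = sel$evaluation$fitness, error = sel$evaluation$err,
                    size = sum(sel$evaluation$mask), seed = run_seed)
        metrics[j, alg] <- rec$fitness
        curve <- sel$result$curve
      } else {
        tr <- train_mlp_with_optimizer(data_j, algorithm = alg, params = pars,
                                       seed = run_seed)
        rec <- list(fitness = tr$result$best_fitness, error = 1 - tr$test_accuracy,
                    size = n_weights(tr$model$architecture), seed = run_seed)
        metrics[j, alg] <- tr$test_accuracy
        curve <- tr$result$curve
      }
      runs[[alg]] <- c(runs[[alg]], list(rec))
      curves[[length(curves) + 1L]] <- data.frame(
        algorithm = alg, run = j, iteration = seq_along(curve), best_fitness = curve)
    }
  }

  D <- ncol(data_generator(as.integer(seed) + 1L)$X)
  summary_tab <- do.call(rbind, lapply(algorithms, function(alg) {
    cbind(data.frame(algorithm = alg), fs_run_statistics(runs[[alg]], D))
  }))
  if (task == "mlp") {
    summary_tab$mean_accuracy <- colMeans(metrics)[summary_tab$algorithm]
    summary_tab$sd_accuracy <- apply(metrics, 2, stats::sd)[summary_tab$algorithm]
  }

  ref <- algorithms[1]
  wil <- do.call(rbind, lapply(algorithms[-1], function(alg) {
    w <- wilcoxon_rank_sum(metrics[, ref], metrics[, alg])
    data.frame(reference = ref, algorithm = alg,
               statistic = w$statistic, p_value = w$p_value, method = w$method)
  }))
  aov_res <- tryCatch(anova_one_way(lapply(algorithms, function(a) metrics[, a])),
                      error = function(e) NULL)

  out <- structure(list(task = task, metric = metric_name, metrics = metrics,
                        summary = summary_tab, wilcoxon = wil, anova = aov_res,
                        curves = do.call(rbind, curves), seed = as.integer(seed)),
                   class = "algorithm_comparison")
  if (!is.null(output_dir)) write_comparison(out, output_dir)
  out
}

#' @export
print.algorithm_comparison <- function(x, ...) {
  cat(sprintf("<algorithm_comparison> task '%s', %d algorithms x %d paired runs (metric: %s)\n\n",
              x$task, ncol(x$metrics), nrow(x$metrics), x$metric))
  print(x$summary, row.names = FALSE)
  cat("\nPairwise Wilcoxon rank-sum vs", x$wilcoxon$reference[1], "\n")
  print(x$wilcoxon[, c("algorithm", "statistic", "p_value")], row.names = FALSE)
  if (!is.null(x$anova)) {
    cat(sprintf("\nOne-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
                x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p_value))
  }
  invisible(x)
}

#' Write comparison tables to a directory
#'
#' Writes `summary.csv`, `wilcoxon.csv`, `anova.csv`, `curves.csv` and a
#' human-readable `summary.md`.
#'
#' @param cmp An `algorithm_comparison`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(cmp, dir) {
  stopifnot(inherits(cmp, "algorithm_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cmp$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(cmp$wilcoxon, file.path(dir, "wilcoxon.csv"), row.names = FALSE)
  if (!is.null(cmp$anova)) {
    utils::write.csv(data.frame(F = cmp$anova$F, df1 = cmp$anova$df[1],
                                df2 = cmp$anova$df[2], p_value = cmp$anova$p_value,
                                ss_between = cmp$anova$ss_between,
                                ss_within = cmp$anova$ss_within),
                     file.path(dir, "anova.csv"), row.names = FALSE)
  }
  utils::write.csv(cmp$curves, file.path(dir, "curves.csv"), row.names = FALSE)

  md <- c(sprintf("# Optimizer comparison (%s task)", cmp$task),
          "",
          sprintf("%d paired runs per algorithm; metric: %s; base seed %d.",
                  nrow(cmp$metrics), cmp$metric, cmp$seed),
          "",
          "## Per-algorithm statistics", "",
          paste(utils::capture.output(print(cmp$summary, row.names = FALSE)),
                collapse = "\n"),
          "",
          sprintf("## Wilcoxon rank-sum vs %s", cmp$wilcoxon$reference[1]), "",
          paste(utils::capture.output(print(
            cmp$wilcoxon[, c("algorithm", "statistic", "p_value")],
            row.names = FALSE)), collapse = "\n"))
  if (!is.null(cmp$anova)) {
    md <- c(md, "", sprintf("One-way ANOVA: F(%d, %d) = %.6g, p = %.6g",
                            cmp$anova$df[1], cmp$anova$df[2],
                            cmp$anova$F, cmp$anova$p_value))
  }
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}
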