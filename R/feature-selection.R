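#' Wrapper feature-selection configuration
#'
#' `h1` weighs the classification error against the selected-subset size in
#' the selection fitness (`h2 = 1 - h1`); the error oracle is a classifier
#' trained on the train split and scored on the validation split. The default
#' k-nearest-neighbour oracle (k = 5, Euclidean, majority vote) is fully
#' deterministic: nearest-neighbour ties go to the lower train-row index and
#' vote ties to the lower class index. The `"mlp"` oracle trains a small
#' single-hidden-layer network (via \pkg{nnet}) under a preserved RNG state.
#'
#' @param h1 Error weight in \[0, 1\]; the subset-size weight is `1 - h1`.
#' @param classifier `"knn"` (default) or `"mlp"`.
#' @param k Neighbours for the knn oracle.
#' @param empty_mask Policy when no feature is selected: `"worst"` scores
#'   error 1.0 (default); `"force-one"` selects the single best scoring
#'   feature instead.
#' @return An object of class `fs_config`.
#' @export
fs_config <- function(h1 = 0.99, classifier = c("knn", "mlp"), k = 5L,
                      empty_mask = c("worst", "force-one")) {
  if (h1 < 0 || h1 > 1) stop("`h1` must lie in [0, 1]", call. = FALSE)
  structure(list(h1 = h1, h2 = 1 - h1, classifier = match.arg(classifier),
                 k = as.integer(k), empty_mask = match.arg(empty_mask)),
            class = "fs_config")
}

#' Sigmoid binarization of a continuous position
#'
#' Transfer function mapping each continuous component to a feature-selection
#' bit: component `j` is selected iff `1 / (1 + exp(-10 (x_j - 0.5))) >= 0.5`,
#' which holds exactly when `x_j >= 0.5`.
#'
#' @param x Numeric vector with finite entries.
#' @return Integer 0/1 vector of the same length.
#' @examples
#' binarize(c(0, 0.5, 0.7))  # 0 1 1
#' @export
binarize <- function(x) {
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  s <- 1 / (1 + exp(-10 * (x - 0.5)))
  as.integer(s >= 0.5)
}

#' Selection fitness combining error rate and subset size
#'
#' `F = h1 * err + (1 - h1) * |selected| / D`: with the default `h1 = 0.99`
#' the classification error dominates and the subset-size term breaks ties
#' between equally accurate subsets in favour of smaller ones.
#'
#' @param err Classification error rate in \[0, 1\].
#' @param mask Binary selection vector of length D.
#' @param h1 Error weight in \[0, 1\].
#' @return The fitness value in \[0, 1\].
#' @examples
#' fs_fitness(0.2113, rep(c(1, 0), 4), h1 = 0.99)
#' @export
fs_fitness <- function(err, mask, h1 = 0.99) {
  if (h1 < 0 || h1 > 1) stop("`h1` must lie in [0, 1]", call. = FALSE)
  if (err < 0 || err > 1) stop("`err` must lie in [0, 1]", call. = FALSE)
  h1 * err + (1 - h1) * sum(mask != 0) / length(mask)
}

# deterministic k-nearest-neighbour error; P is the per-feature squared
# difference array built by prep_knn (D x (nva*ntr))
prep_knn <- function(data) {
  tr <- data$split$train
  va <- data$split$validation
  Xtr <- data$X[tr, , drop = FALSE]
  Xva <- data$X[va, , drop = FALSE]
  D <- ncol(data$X)
  nva <- length(va); ntr <- length(tr)
  P <- matrix(NA_real_, D, nva * ntr)
  for (j in seq_len(D)) {
    P[j, ] <- as.vector(outer(Xva[, j], Xtr[, j], "-")^2)
  }
  list(P = P, ytr = as.integer(data$y[tr]), yva = as.integer(data$y[va]),
       nva = nva, ntr = ntr, K = nlevels(data$y))
}

knn_error_masked <- function(prep, mask, k) {
  sel <- which(mask != 0)
  d2 <- matrix(if (length(sel) == 1L) prep$P[sel, ] else colSums(prep$P[sel, , drop = FALSE]),
               prep$nva, prep$ntr)
  k <- min(k, prep$ntr)
  wrong <- 0L
  for (i in seq_len(prep$nva)) {
    nb <- order(d2[i, ])[seq_len(k)]      # stable: distance ties -> lower train index
    votes <- tabulate(prep$ytr[nb], nbins = prep$K)
    if (which.max(votes) != prep$yva[i]) wrong <- wrong + 1L
  }
  wrong / prep$nva
}

# run expr under set.seed(seed) without disturbing the caller's RNG stream
with_preserved_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

mlp_oracle_error <- function(data, sel, seed) {
  tr <- data$split$train
  va <- data$split$validation
  Xtr <- data$X[tr, sel, drop = FALSE]
  Xva <- data$X[va, sel, drop = FALSE]
  sc <- minmax_fit(Xtr)
  Xtr <- minmax_scale(Xtr, sc$mins, sc$maxs)
  Xva <- minmax_scale(Xva, sc$mins, sc$maxs)
  fit <- with_preserved_rng(seed, {
    utils::capture.output(
      m <- nnet::nnet(Xtr, stats::model.matrix(~ data$y[tr] - 1),
                      size = max(2L, min(8L, length(sel))), maxit = 100,
                      trace = FALSE, softmax = FALSE, linout = FALSE)
    )
    m
  })
  scores <- stats::predict(fit, Xva)
  pred <- max.col(scores, ties.method = "first")
  mean(pred != as.integer(data$y[va]))
}

#' Validation error of a feature subset
#'
#' Trains the configured wrapper classifier on the train split restricted to
#' the selected columns and returns its misclassification rate on the
#' validation split. An empty mask is handled by the configured policy
#' (default: worst-case error 1.0), never an error.
#'
#' @param data A `feature_dataset`.
#' @param mask Binary vector, one entry per feature.
#' @param cfg An [fs_config()].
#' @param seed Seed used by stochastic oracles (the knn oracle is
#'   deterministic and ignores it).
#' @return Error rate in \[0, 1\].
#' @export
subset_error <- function(data, mask, cfg = fs_config(), seed = 1L) {
  stopifnot(inherits(data, "feature_dataset"))
  if (length(mask) != ncol(data$X)) {
    stop(sprintf("`mask` must have length %d (one entry per feature)", ncol(data$X)),
         call. = FALSE)
  }
  if (sum(mask != 0) == 0) {
    if (cfg$empty_mask == "worst") return(1.0)
    mask <- integer(length(mask))
    mask[best_single_feature(data, cfg)] <- 1L
  }
  if (cfg$classifier == "knn") {
    prep <- prep_knn(data)
    knn_error_masked(prep, mask, cfg$k)
  } else {
    mlp_oracle_error(data, which(mask != 0), seed)
  }
}

best_single_feature <- function(data, cfg) {
  prep <- prep_knn(data)
  errs <- vapply(seq_len(ncol(data$X)), function(j) {
    m <- integer(ncol(data$X)); m[j] <- 1L
    knn_error_masked(prep, m, cfg$k)
  }, numeric(1))
  which.min(errs)
}

#' Build the continuous feature-selection objective
#'
#' Returns a function over `[0, 1]^D` pluggable into [run_optimizer()]:
#' the position is binarized through the sigmoid transfer function and scored
#' by `h1 * err + h2 * |s|/D`. Because the objective depends on the position
#' only through its mask, evaluations are memoized per mask; the cache
#' environment is attached as attribute `"cache"` with counters `n_calls`
#' (objective invocations) and `n_evals` (distinct masks actually scored).
#'
#' @inheritParams subset_error
#' @return A function `numeric(D) -> numeric(1)`.
#' @export
make_fs_objective <- function(data, cfg = fs_config(), seed = 1L) {
  stopifnot(inherits(data, "feature_dataset"))
  prep <- if (cfg$classifier == "knn") prep_knn(data) else NULL
  cache <- new.env(parent = emptyenv())
  cache$n_calls <- 0L
  cache$n_evals <- 0L
  D <- ncol(data$X)
  obj <- function(x) {
    mask <- binarize(x)
    key <- paste(mask, collapse = "")
    cache$n_calls <- cache$n_calls + 1L
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    err <- if (sum(mask) == 0 || is.null(prep)) {
      subset_error(data, mask, cfg, seed)
    } else {
      knn_error_masked(prep, mask, cfg$k)
    }
    val <- fs_fitness(err, mask, cfg$h1)
    assign(key, val, envir = cache)
    cache$n_evals <- cache$n_evals + 1L
    val
  }
  attr(obj, "cache") <- cache
  obj
}

#' Exhaustively find the best feature subset (testing oracle)
#'
#' Scores every non-empty mask (plus the empty-mask policy) with the same
#' error oracle and fitness as [make_fs_objective()] and returns the global
#' minimizer; ties go to the lexicographically smallest mask. Guarded to
#' `D <= 20`; it exists as a ground-truth oracle for small problems, not as a
#' practical selector.
#'
#' @inheritParams subset_error
#' @return An object of class `subset_evaluation`: `mask`, `err`, `ratio`,
#'   `fitness`.
#' @export
exhaustive_best_subset <- function(data, cfg = fs_config(), seed = 1L) {
  stopifnot(inherits(data, "feature_dataset"))
  D <- ncol(data$X)
  if (D > 20) {
    stop("exhaustive enumeration is guarded to D <= 20 (2^D subsets); use an optimizer instead",
         call. = FALSE)
  }
  prep <- if (cfg$classifier == "knn") prep_knn(data) else NULL
  best <- NULL
  # masks in lexicographic order (feature 1 = most significant bit), so the
  # first strict improvement wins and ties resolve to the smallest mask
  for (m in seq_len(2^D - 1)) {
    mask <- rev(as.integer(intToBits(m))[seq_len(D)])
    err <- if (is.null(prep)) subset_error(data, mask, cfg, seed)
           else knn_error_masked(prep, mask, cfg$k)
    fit <- fs_fitness(err, mask, cfg$h1)
    if (is.null(best) || fit < best$fitness) {
      best <- list(mask = mask, err = err, ratio = sum(mask) / D, fitness = fit)
    }
  }
  if (cfg$empty_mask == "worst") {
    empty_fit <- fs_fitness(1.0, integer(D), cfg$h1)
    if (empty_fit < best$fitness) {
      best <- list(mask = integer(D), err = 1.0, ratio = 0, fitness = empty_fit)
    }
  }
  structure(best, class = "subset_evaluation")
}

#' @export
print.subset_evaluation <- function(x, ...) {
  cat(sprintf("<subset_evaluation> %d/%d features, error %.4f, fitness %.6f\n",
              sum(x$mask), length(x$mask), x$err, x$fitness))
  invisible(x)
}

#' Select features with a metaheuristic wrapper
#'
#' Runs a registered optimizer over the continuous space `[0, 1]^D` with the
#' sigmoid-binarized wrapper objective and returns the selected mask with its
#' validation error and fitness.
#'
#' @param data A `feature_dataset`.
#' @param algorithm Optimizer name (see [registered_algorithms()]).
#' @param params Optimizer parameters; `NULL` uses the algorithm defaults.
#' @param cfg An [fs_config()].
#' @param seed Run seed.
#' @return List with `evaluation` (a `subset_evaluation`), `result` (the
#'   `optimizer_result`), and `selected` (feature names).
#' @export
select_features <- function(data, algorithm = "assoa", params = NULL,
                            cfg = fs_config(), seed = 1L) {
  D <- ncol(data$X)
  space <- search_space(D, 0, 1, mode = "binary-from-continuous")
  obj <- make_fs_objective(data, cfg, seed)
  res <- run_optimizer(algorithm, space, obj, params, seed = seed)
  mask <- binarize(res$best_position)
  err <- subset_error(data, mask, cfg, seed)
  ev <- structure(list(mask = mask, err = err, ratio = sum(mask) / D,
                       fitness = fs_fitness(err, mask, cfg$h1)),
                  class = "subset_evaluation")
  list(evaluation = ev, result = res,
       selected = data$feature_names[mask == 1])
}

#' Write a selection mask as CSV
#'
#' Two columns: `feature_name`, `selected` (0/1).
#'
#' @param data The `feature_dataset` the mask refers to.
#' @param mask Binary vector.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_mask_csv <- function(data, mask, path) {
  utils::write.csv(data.frame(feature_name = data$feature_names,
                              selected = as.integer(mask != 0)),
                   path, row.names = FALSE)
  invisible(path)
}
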