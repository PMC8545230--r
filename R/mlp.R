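#' Min-max feature scaling
#'
#' `minmax_fit` records the per-feature minimum and maximum of a training
#' matrix; `minmax_scale` applies `(x - min) / (max - min)` component-wise.
#' A constant feature (`max == min`) maps to 0; values outside the training
#' range extrapolate beyond \[0, 1\] (no re-clipping).
#'
#' @param X Numeric training matrix (samples x features).
#' @return `minmax_fit`: list with `mins`, `maxs`.
#' @export
minmax_fit <- function(X) {
  X <- as.matrix(X)
  list(mins = apply(X, 2, min), maxs = apply(X, 2, max))
}

#' @rdname minmax_fit
#' @param x Numeric vector (one sample) or matrix to scale.
#' @param mins,maxs Per-feature training minima and maxima.
#' @return `minmax_scale`: the scaled vector or matrix.
#' @examples
#' minmax_scale(c(0, 5, 10), mins = 0, maxs = 10)
#' @export
minmax_scale <- function(x, mins, maxs) {
  if (any(maxs < mins)) stop("`maxs` must be >= `mins`", call. = FALSE)
  rng <- maxs - mins
  safe <- ifelse(rng == 0, 1, rng)
  if (is.matrix(x)) {
    out <- sweep(sweep(x, 2, mins, "-"), 2, safe, "/")
    out[, rng == 0] <- 0
  } else {
    out <- (x - mins) / safe
    out[rng == 0] <- 0
  }
  out
}

#' Single-hidden-layer perceptron architecture
#'
#' The classifier is a perceptron with one hidden layer: hidden pre-activation
#' `S_j = sum_i w_ij x_i + b_j`, sigmoid hidden activation
#' `f_j = 1/(1 + exp(-S_j))`, and a linear output layer
#' `y_k = sum_j w_jk f_j + b_k` (no softmax); the predicted class is the
#' argmax of the output scores with ties going to the lower class index.
#' Connection weights live in \[-1, 1\] and are found by metaheuristic search,
#' not backpropagation.
#'
#' @param n_in Number of inputs (features).
#' @param m_hidden Hidden width; default `2 * n_in + 1`.
#' @param n_out Number of outputs (classes, one-vs-all encoding).
#' @return An object of class `mlp_architecture`.
#' @export
mlp_architecture <- function(n_in, m_hidden = 2 * n_in + 1, n_out = 2) {
  stopifnot(n_in >= 1, m_hidden >= 1, n_out >= 1)
  structure(list(n_in = as.integer(n_in), m_hidden = as.integer(m_hidden),
                 n_out = as.integer(n_out)), class = "mlp_architecture")
}

#' Length of the flat weight vector of an architecture
#' @param arch An [mlp_architecture()].
#' @return Integer: `n_in*m + m + m*n_out + n_out`.
#' @export
n_weights <- function(arch) {
  with(arch, n_in * m_hidden + m_hidden + m_hidden * n_out + n_out)
}

#' Flat weight-vector codec
#'
#' The optimizer searches a flat vector; the fixed layout is
#' `[w_ij row-major, b_j, w_jk row-major, b_k]` (rows = source units).
#' `decode_weights(encode_weights(...))` is bit-exact.
#'
#' @param arch An [mlp_architecture()].
#' @param w Flat numeric vector of length [n_weights()].
#' @return `decode_weights`: list with `W1` (n_in x m), `b1`, `W2`
#'   (m x n_out), `b2`.
#' @export
decode_weights <- function(arch, w) {
  want <- n_weights(arch)
  if (length(w) != want) {
    stop(sprintf("weight vector has length %d; architecture (%d,%d,%d) needs %d",
                 length(w), arch$n_in, arch$m_hidden, arch$n_out, want), call. = FALSE)
  }
  n <- arch$n_in; m <- arch$m_hidden; K <- arch$n_out
  i <- 0L
  W1 <- matrix(w[i + seq_len(n * m)], n, m, byrow = TRUE); i <- i + n * m
  b1 <- w[i + seq_len(m)]; i <- i + m
  W2 <- matrix(w[i + seq_len(m * K)], m, K, byrow = TRUE); i <- i + m * K
  b2 <- w[i + seq_len(K)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

#' @rdname decode_weights
#' @param W1,b1,W2,b2 Layer weights and biases with matching shapes.
#' @return `encode_weights`: the flat vector.
#' @export
encode_weights <- function(arch, W1, b1, W2, b2) {
  stopifnot(nrow(W1) == arch$n_in, ncol(W1) == arch$m_hidden,
            length(b1) == arch$m_hidden,
            nrow(W2) == arch$m_hidden, ncol(W2) == arch$n_out,
            length(b2) == arch$n_out)
  c(as.vector(t(W1)), b1, as.vector(t(W2)), b2)
}

#' Forward pass of the perceptron
#'
#' @param arch An [mlp_architecture()].
#' @param w Flat weight vector.
#' @param X One sample (length `n_in` vector) or a samples x `n_in` matrix.
#' @return Matrix of class scores (samples x `n_out`).
#' @export
mlp_forward <- function(arch, w, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != arch$n_in) {
    stop(sprintf("input has %d columns; architecture expects %d", ncol(X), arch$n_in),
         call. = FALSE)
  }
  L <- decode_weights(arch, w)
  S <- sweep(X %*% L$W1, 2, L$b1, "+")
  f <- 1 / (1 + exp(-S))
  sweep(f %*% L$W2, 2, L$b2, "+")
}

# argmax class with lower-index tie rule
score_to_class <- function(scores) max.col(scores, ties.method = "first")

#' Build the MLP weight-training objective
#'
#' Returns `objective(w) =` misclassification rate of the decoded network,
#' inputs min-max scaled with train-split statistics. This is the fitness the
#' metaheuristic minimizes when training connection weights; no gradient is
#' ever taken. Because the search itself is the training procedure, the
#' default fitness sample is the development set (train plus validation
#' rows): the empirical error is the only training signal, and measuring it
#' on the largest non-test sample keeps its quantization fine. The test split
#' is never touched here.
#'
#' @param data A `feature_dataset`.
#' @param arch An [mlp_architecture()] with `n_in == ncol(data$X)`.
#' @param fitness_split Rows the error is measured on: `"development"`
#'   (train + validation, default), `"validation"`, or `"train"`.
#' @return A function `numeric(n_weights) -> numeric(1)` in \[0, 1\].
#' @export
make_mlp_objective <- function(data, arch,
                               fitness_split = c("development", "validation", "train")) {
  stopifnot(inherits(data, "feature_dataset"), inherits(arch, "mlp_architecture"))
  fitness_split <- match.arg(fitness_split)
  if (arch$n_in != ncol(data$X)) {
    stop("`arch$n_in` must equal the number of features", call. = FALSE)
  }
  sc <- minmax_fit(data$X[data$split$train, , drop = FALSE])
  idx <- switch(fitness_split,
                development = c(data$split$train, data$split$validation),
                validation = data$split$validation,
                train = data$split$train)
  Xf <- minmax_scale(data$X[idx, , drop = FALSE], sc$mins, sc$maxs)
  yf <- as.integer(data$y[idx])
  function(w) {
    pred <- score_to_class(mlp_forward(arch, w, Xf))
    mean(pred != yf)
  }
}

#' Train perceptron weights with a metaheuristic
#'
#' Searches `[-1, 1]^n_weights` with the chosen optimizer for the weight
#' vector minimizing the validation misclassification rate, then freezes the
#' best network together with the train-split min-max scaling and the label
#' encoding, and scores the held-out test split once.
#'
#' @param data A `feature_dataset`.
#' @param arch An [mlp_architecture()]; `NULL` uses all features, hidden
#'   width `2*n_in + 1`, and one output per class.
#' @param algorithm Optimizer name.
#' @param params Optimizer parameters; `NULL` uses algorithm defaults.
#' @param seed Run seed.
#' @param fitness_split Passed to [make_mlp_objective()].
#' @return List with `model` (a `trained_mlp`), `result` (the
#'   `optimizer_result`), and `test_accuracy`.
#' @export
train_mlp_with_optimizer <- function(data, arch = NULL, algorithm = "assoa",
                                     params = NULL, seed = 1L,
                                     fitness_split = "development") {
  stopifnot(inherits(data, "feature_dataset"))
  if (is.null(arch)) arch <- mlp_architecture(ncol(data$X), n_out = nlevels(data$y))
  space <- search_space(n_weights(arch), -1, 1)
  obj <- make_mlp_objective(data, arch, fitness_split)
  res <- run_optimizer(algorithm, space, obj, params, seed = seed)
  sc <- minmax_fit(data$X[data$split$train, , drop = FALSE])
  model <- structure(list(architecture = arch, weights = res$best_position,
                          mins = sc$mins, maxs = sc$maxs,
                          levels = levels(data$y)), class = "trained_mlp")
  te <- data$split$test
  pred <- predict(model, data$X[te, , drop = FALSE])
  list(model = model,
       result = res,
       test_accuracy = mean(pred == as.character(data$y[te])))
}

#' @export
print.trained_mlp <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("<trained_mlp> %d-%d-%d (%d weights), classes: %s\n",
              a$n_in, a$m_hidden, a$n_out, n_weights(a),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict with a trained perceptron
#'
#' @param object A `trained_mlp`.
#' @param newdata Matrix of raw (unscaled) features.
#' @param type `"class"` for labels, `"score"` for the raw output scores.
#' @param ... Unused.
#' @return Character vector of labels, or a score matrix.
#' @export
predict.trained_mlp <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- minmax_scale(as.matrix(newdata), object$mins, object$maxs)
  scores <- mlp_forward(object$architecture, object$weights, X)
  colnames(scores) <- object$levels
  if (type == "score") return(scores)
  object$levels[score_to_class(scores)]
}

#' Serialize / load a trained perceptron as JSON
#'
#' Stores the architecture, flat weights, min-max scaling parameters and the
#' label map.
#'
#' @param model A `trained_mlp`.
#' @param path JSON path.
#' @return `write_mlp_json`: the path, invisibly; `read_mlp_json`: a
#'   `trained_mlp`.
#' @export
write_mlp_json <- function(model, path) {
  stopifnot(inherits(model, "trained_mlp"))
  jsonlite::write_json(list(
    architecture = unclass(model$architecture),
    weights = model$weights,
    mins = model$mins, maxs = model$maxs,
    levels = model$levels
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    architecture = mlp_architecture(j$architecture$n_in, j$architecture$m_hidden,
                                    j$architecture$n_out),
    weights = as.numeric(j$weights),
    mins = as.numeric(j$mins), maxs = as.numeric(j$maxs),
    levels = as.character(j$levels)
  ), class = "trained_mlp")
}
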