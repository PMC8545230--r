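#' Construct a labeled feature dataset with a 60/20/20 split
#'
#' The container every wrapper-selection and classifier-training function
#' consumes: a numeric samples-by-features matrix, a class label per sample,
#' and a stratified train (60%) / validation (20%) / test (20%) split of the
#' rows. Wrapper error is measured on the validation rows; test rows are
#' touched only once, for final metrics.
#'
#' @param X Numeric matrix (samples x features), no missing values.
#' @param y Class labels, at least 2 distinct values; coerced to factor.
#' @param feature_names Optional feature names; defaults to `colnames(X)` or
#'   `f1..fD`.
#' @param split Optional list with integer row indices `train`, `validation`,
#'   `test`; when `NULL` a stratified split is drawn with `seed`.
#' @param seed Seed for the stratified split when `split` is `NULL`.
#' @param proportions Split proportions, default `c(0.6, 0.2, 0.2)`.
#' @return An object of class `feature_dataset`.
#' @export
feature_dataset <- function(X, y, feature_names = NULL, split = NULL, seed = 1L,
                            proportions = c(0.6, 0.2, 0.2)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("`X` must not contain missing values", call. = FALSE)
  y <- as.factor(y)
  if (length(y) != nrow(X)) stop("`y` must have one label per row of `X`", call. = FALSE)
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  }
  colnames(X) <- feature_names
  if (is.null(split)) split <- stratified_split(y, proportions, seed)
  stopifnot(all(c("train", "validation", "test") %in% names(split)))
  idx <- c(split$train, split$validation, split$test)
  if (anyDuplicated(idx) || !setequal(idx, seq_len(nrow(X)))) {
    stop("split must partition the rows disjointly", call. = FALSE)
  }
  if (any(lengths(split[c("train", "validation", "test")]) == 0)) {
    stop("every split must be non-empty", call. = FALSE)
  }
  structure(list(X = X, y = y, feature_names = feature_names, split = split),
            class = "feature_dataset")
}

#' Stratified train/validation/test split
#'
#' Rows of each class are shuffled and allocated to the three splits in the
#' given proportions (rounded per class; the remainder goes to test).
#'
#' @param y Factor of class labels.
#' @param proportions Length-3 positive proportions summing to 1.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @export
stratified_split <- function(y, proportions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(proportions) == 3, all(proportions > 0),
            abs(sum(proportions) - 1) < 1e-8)
  y <- as.factor(y)
  set.seed(as.integer(seed))
  tr <- va <- te <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    n_c <- length(idx)
    n_tr <- round(proportions[1] * n_c)
    n_va <- round(proportions[2] * n_c)
    n_te <- n_c - n_tr - n_va
    if (n_te < 0) { n_va <- n_va + n_te; n_te <- 0 }
    tr <- c(tr, idx[seq_len(n_tr)])
    va <- c(va, idx[n_tr + seq_len(n_va)])
    te <- c(te, idx[n_tr + n_va + seq_len(n_te)])
  }
  list(train = sort(tr), validation = sort(va), test = sort(te))
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d samples x %d features, %d classes (%s); split %d/%d/%d\n",
              nrow(x$X), ncol(x$X), nlevels(x$y),
              paste(levels(x$y), collapse = ", "),
              length(x$split$train), length(x$split$validation), length(x$split$test)))
  invisible(x)
}

#' Write / read a feature dataset as CSV
#'
#' The CSV has one header row, all feature columns, and the label column named
#' `label_column`. Reading re-derives the stratified split from `seed`, so a
#' re-read with the same seed reproduces the split exactly.
#'
#' @param data A `feature_dataset`.
#' @param path CSV path.
#' @param label_column Name of the label column.
#' @return `write_feature_csv`: the path, invisibly. `read_feature_csv`: a
#'   `feature_dataset`.
#' @export
write_feature_csv <- function(data, path, label_column = "label") {
  stopifnot(inherits(data, "feature_dataset"))
  df <- as.data.frame(data$X)
  df[[label_column]] <- as.character(data$y)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param seed Seed for the stratified split of the rows read.
#' @export
read_feature_csv <- function(path, label_column = "label", seed = 1L) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found in %s", label_column, path), call. = FALSE)
  }
  y <- df[[label_column]]
  feats <- df[setdiff(names(df), label_column)]
  for (j in seq_along(feats)) {
    v <- feats[[j]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric value in row %d, column '%s'",
                     bad[1], names(feats)[j]), call. = FALSE)
      }
      feats[[j]] <- coerced
    }
  }
  feature_dataset(as.matrix(feats), y, seed = seed)
}
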