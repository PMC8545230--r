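#' Specification of a planted feature table
#'
#' Describes a synthetic classification dataset with known structure:
#' `k_informative` features whose class means are separated by `delta` noise
#' standard deviations, optional redundant copies of the informative features
#' (plus 10% jitter), and the remaining features pure class-independent noise.
#' Columns are shuffled with a recorded permutation so selection methods
#' cannot exploit position.
#'
#' @param n_samples Total samples, balanced across classes.
#' @param D Total number of features.
#' @param k_informative Number of class-informative features.
#' @param n_classes Number of classes.
#' @param delta Class-mean separation in units of `noise_sd`.
#' @param noise_sd Feature noise standard deviation.
#' @param redundancy Number of redundant (jittered-copy) features.
#' @param seed Integer seed.
#' @return An object of class `planted_spec`.
#' @export
planted_spec <- function(n_samples = 150L, D = 10L, k_informative = 2L,
                         n_classes = 2L, delta = 3, noise_sd = 1,
                         redundancy = 0L, seed = 1L) {
  sp <- list(n_samples = as.integer(n_samples), D = as.integer(D),
             k_informative = as.integer(k_informative),
             n_classes = as.integer(n_classes), delta = delta,
             noise_sd = noise_sd, redundancy = as.integer(redundancy),
             seed = as.integer(seed))
  if (sp$k_informative + sp$redundancy > sp$D) {
    stop("`k_informative` + `redundancy` must not exceed `D`", call. = FALSE)
  }
  if (sp$delta < 0) stop("`delta` must be non-negative", call. = FALSE)
  if (sp$k_informative < 1 || sp$n_classes < 2) {
    stop("need at least 1 informative feature and 2 classes", call. = FALSE)
  }
  structure(sp, class = "planted_spec")
}

#' Generate a planted feature table
#'
#' Pure function of its spec: informative columns are
#' `Normal(class_mean, noise_sd)` with class means `0, delta*noise_sd,
#' 2*delta*noise_sd, ...`; redundant columns are informative columns plus
#' `Normal(0, 0.1*noise_sd)` jitter; the rest is `Normal(0, noise_sd)` noise
#' independent of the class. Ground truth is attached as attributes.
#'
#' @param spec A [planted_spec()].
#' @return A `feature_dataset` with attributes `informative` (column indices
#'   of the informative features after shuffling), `redundant`, and
#'   `permutation` (the recorded column shuffle).
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  y <- factor(rep_len(paste0("class", seq_len(spec$n_classes)), n))
  means <- (as.integer(y) - 1) * spec$delta * spec$noise_sd

  X <- matrix(NA_real_, n, spec$D)
  k <- spec$k_informative
  for (j in seq_len(k)) {
    X[, j] <- stats::rnorm(n, mean = means, sd = spec$noise_sd)
  }
  if (spec$redundancy > 0) {
    for (j in seq_len(spec$redundancy)) {
      src <- ((j - 1) %% k) + 1
      X[, k + j] <- X[, src] + stats::rnorm(n, sd = 0.1 * spec$noise_sd)
    }
  }
  rest <- seq_len(spec$D)[-(seq_len(k + spec$redundancy))]
  for (j in rest) X[, j] <- stats::rnorm(n, sd = spec$noise_sd)

  perm <- sample.int(spec$D)
  X <- X[, perm, drop = FALSE]
  colnames(X) <- paste0("f", seq_len(spec$D))
  out <- feature_dataset(X, y, seed = spec$seed)
  attr(out, "informative") <- match(seq_len(k), perm)
  attr(out, "redundant") <- if (spec$redundancy > 0) match(k + seq_len(spec$redundancy), perm) else integer(0)
  attr(out, "permutation") <- perm
  out
}

#' Generate a linearly separable two-class dataset
#'
#' Samples standard-normal points, projects out their component along a random
#' unit normal vector `w`, and places each class at signed distance at least
#' `margin` from the hyperplane through the origin, so `w` classifies the
#' clean labels perfectly. With `label_noise > 0` that fraction of labels is
#' flipped, bounding the best achievable error from below.
#'
#' @param n Total samples (classes balanced to within one sample).
#' @param d Number of features.
#' @param margin Minimum distance of any point to the separating hyperplane.
#' @param seed Integer seed.
#' @param label_noise Fraction of labels flipped after construction.
#' @return A `feature_dataset` with attribute `hyperplane` (`list(w, b = 0)`).
#' @export
generate_separable <- function(n, d, margin, seed = 1L, label_noise = 0) {
  if (margin <= 0) stop("`margin` must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  w <- stats::rnorm(d)
  w <- w / sqrt(sum(w^2))
  sign_y <- rep_len(c(1, -1), n)
  X <- matrix(stats::rnorm(n * d), n, d)
  proj <- as.vector(X %*% w)
  # remove the along-w component, then place at distance margin + |half-normal|
  X <- X - outer(proj, w)
  dist <- margin + abs(stats::rnorm(n))
  X <- X + outer(sign_y * dist, w)
  y <- factor(ifelse(sign_y > 0, "pos", "neg"), levels = c("neg", "pos"))
  if (label_noise > 0) {
    flip <- stats::runif(n) < label_noise
    y[flip] <- ifelse(y[flip] == "pos", "neg", "pos")
  }
  colnames(X) <- paste0("f", seq_len(d))
  out <- feature_dataset(X, y, seed = seed)
  attr(out, "hyperplane") <- list(w = w, b = 0)
  out
}

#' Generate a CNN-activation-like feature fixture
#'
#' Block-correlated non-negative features built from rectified Gaussian
#' factors: features within a block share a latent factor (high within-block
#' correlation), and a small fraction (5%) of columns carry a mild 3-class
#' mean shift. A statistical stand-in for pooled convolutional activations —
#' synthetic, with no attempt at visual fidelity.
#'
#' @param n Number of samples.
#' @param D Number of features (default 256).
#' @param seed Integer seed.
#' @param n_blocks Number of correlated feature blocks.
#' @return A `feature_dataset` with attribute `blocks` (block index per
#'   column) and `signal_columns`.
#' @export
generate_feature_fixture <- function(n, D = 256L, seed = 1L, n_blocks = 8L) {
  set.seed(as.integer(seed))
  D <- as.integer(D)
  y <- factor(rep_len(paste0("class", 1:3), n))
  block <- rep_len(seq_len(n_blocks), D)
  Z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  n_signal <- max(1L, round(0.05 * D))
  signal_cols <- sort(sample.int(D, n_signal))
  shift <- matrix(0, n, D)
  shift[, signal_cols] <- 0.8 * (as.integer(y) - 2)
  X <- pmax(0.9 * Z[, block] + 0.45 * matrix(stats::rnorm(n * D), n, D) + shift + 1, 0)
  colnames(X) <- paste0("f", seq_len(D))
  out <- feature_dataset(X, y, seed = seed)
  attr(out, "blocks") <- block
  attr(out, "signal_columns") <- signal_cols
  out
}
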