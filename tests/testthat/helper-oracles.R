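# Independent oracles used across tests; deliberately written from first
# principles, not by calling the implementation under test.

# brute-force two-sided rank-sum p over all group assignments of the pooled
# midranks (doubled smaller tail, capped at 1)
brute_force_rank_sum_p <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  W_all <- apply(combos, 2, function(ix) sum(r[ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(W_all <= W + eps), mean(W_all >= W - eps)))
}

# naive per-neuron perceptron evaluation (spreadsheet-style), independent of
# the vectorized forward pass
naive_mlp_forward <- function(W1, b1, W2, b2, x) {
  m <- length(b1); K <- length(b2)
  f <- numeric(m)
  for (j in seq_len(m)) {
    s <- b1[j]
    for (i in seq_along(x)) s <- s + W1[i, j] * x[i]
    f[j] <- 1 / (1 + exp(-s))
  }
  y <- numeric(K)
  for (k in seq_len(K)) {
    y[k] <- b2[k]
    for (j in seq_len(m)) y[k] <- y[k] + W2[j, k] * f[j]
  }
  y
}

# tiny two-class dataset where feature 1 separates the classes perfectly and
# the remaining features are noise
tiny_separable_dataset <- function(n = 40, d = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- ifelse(y == "a", -3, 3) + rnorm(n, sd = 0.1)
  feature_dataset(X, y, seed = seed)
}
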