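#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks are used for ties. For small pooled samples (`m + n <= 20`) the
#' p-value is exact: from the null Wilcoxon distribution when the pooled
#' values are tie-free, otherwise by full enumeration of all
#' `choose(m+n, m)` group assignments of the midranks. For larger samples the
#' normal approximation with tie-corrected variance and a continuity
#' correction is used. The two-sided p doubles the smaller tail, capped at 1.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @return List with `statistic` (the Mann-Whitney U of `a`), `rank_sum`
#'   (the rank sum W of `a`), `p_value`, and `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  m <- length(a); n <- length(b); N <- m + n
  pooled <- c(a, b)
  if (any(!is.finite(pooled))) stop("samples must be finite", call. = FALSE)
  r <- rank(pooled)                       # midranks
  W <- sum(r[seq_len(m)])
  U <- W - m * (m + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (N <= 20 && !ties) {
    p <- 2 * min(stats::pwilcox(U, m, n), 1 - stats::pwilcox(U - 1, m, n))
    method <- "exact (Wilcoxon distribution)"
  } else if (N <= 20) {
    combos <- utils::combn(N, m)
    W_perm <- colSums(matrix(r[combos], nrow = m))
    eps <- 1e-9
    p <- 2 * min(mean(W_perm <= W + eps), mean(W_perm >= W - eps))
    method <- "exact (enumeration with midranks)"
  } else {
    mu <- m * n / 2
    tie_tab <- table(pooled)
    sigma2 <- (m * n / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    cc <- if (U == mu) 0 else 0.5 * sign(U - mu)
    z <- (U - mu - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (continuity + tie correction)"
  }
  list(statistic = U, rank_sum = W, p_value = min(1, p), method = method)
}

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition, F with
#' `(k - 1, N - k)` degrees of freedom (fitted through `stats::lm`).
#'
#' @param groups List of at least 2 numeric vectors, each of length at
#'   least 2, with positive total variance.
#' @return List with `F`, `df`, `p_value`, `ss_between`, `ss_within`,
#'   `ss_total`.
#' @export
anova_one_way <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("`groups` must be a list of at least 2 numeric vectors", call. = FALSE)
  }
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(y))) stop("values must be finite", call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) stop("degenerate input: total variance is zero", call. = FALSE)
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab$`F value`[1],
       df = c(tab$Df[1], tab$Df[2]),
       p_value = tab$`Pr(>F)`[1],
       ss_between = tab$`Sum Sq`[1],
       ss_within = tab$`Sum Sq`[2],
       ss_total = ss_total)
}

#' Summary statistics of repeated feature-selection runs
#'
#' For `M` runs of one optimizer: mean error, mean relative selected size
#' (`mean(size)/D`), and the mean, best (min), worst (max) and standard
#' deviation (denominator `M - 1`) of the fitness.
#'
#' @param runs List of runs, each a list with `fitness`, `error`, `size`.
#' @param D Total number of features.
#' @return One-row data frame of the statistics.
#' @export
fs_run_statistics <- function(runs, D) {
  if (length(runs) < 1) stop("need at least one run", call. = FALSE)
  fit <- vapply(runs, `[[`, numeric(1), "fitness")
  err <- vapply(runs, `[[`, numeric(1), "error")
  size <- vapply(runs, `[[`, numeric(1), "size")
  data.frame(runs = length(runs),
             mean_error = mean(err),
             mean_select_size = mean(size) / D,
             mean_fitness = mean(fit),
             best_fitness = min(fit),
             worst_fitness = max(fit),
             sd_fitness = if (length(fit) > 1) stats::sd(fit) else 0)
}
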