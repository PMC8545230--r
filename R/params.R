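#' Squirrel search parameters
#'
#' Constants of the basic squirrel search algorithm. The gliding constant
#' `G_c = 1.9` scales glide moves toward better agents; the predator presence
#' probability `P_dp = 0.1` is the chance that an agent abandons its glide and
#' relocates uniformly at random; `beta = 1.5` is the Lévy exponent of the
#' seasonal relocation; the random gliding distance `d_g` is drawn uniformly
#' from `[dg_low, dg_high]` per move.
#'
#' @param n Population size (>= 5).
#' @param t_m Maximum iterations (>= 1).
#' @param G_c Gliding constant.
#' @param P_dp Predator presence probability in (0, 1).
#' @param beta Lévy exponent in (0, 2].
#' @param dg_low,dg_high Gliding-distance sampling range.
#' @return An object of class `ss_params`.
#' @export
ss_params <- function(n = 10L, t_m = 100L, G_c = 1.9, P_dp = 0.1, beta = 1.5,
                      dg_low = 0.5, dg_high = 1.11) {
  p <- list(n = as.integer(n), t_m = as.integer(t_m), G_c = G_c, P_dp = P_dp,
            beta = beta, dg_low = dg_low, dg_high = dg_high)
  validate_ss_params(p)
  structure(p, class = "ss_params")
}

validate_ss_params <- function(p) {
  if (p$n < 5) stop("`n` must be at least 5", call. = FALSE)
  if (p$t_m < 1) stop("`t_m` must be at least 1", call. = FALSE)
  if (!(p$P_dp > 0 && p$P_dp < 1)) stop("`P_dp` must lie strictly in (0, 1)", call. = FALSE)
  if (p$dg_low > p$dg_high) stop("`dg_low` must not exceed `dg_high`", call. = FALSE)
  if (p$beta <= 0 || p$beta > 2) stop("`beta` must lie in (0, 2]", call. = FALSE)
  invisible(p)
}

#' Advanced squirrel search (ASSOA) parameters
#'
#' Extends [ss_params()] with the gate of the advanced movement block: with
#' probability given by the per-iteration draw `p`, the basic glide cases run
#' (`p >= p_threshold`); otherwise the normal agents move diagonally,
#' vertically/horizontally, or exponentially. `p_fixed`, `a_fixed`, `d_fixed`
#' pin the corresponding per-iteration random draws for deterministic branch
#' testing and are `NULL` (drawn uniform) in normal use.
#'
#' @inheritParams ss_params
#' @param p_threshold Gate for the basic-glide branch, default 0.5.
#' @param p_fixed,a_fixed,d_fixed Optional pinned values for the per-iteration
#'   draws `p`, `a` and the vertical/horizontal threshold.
#' @param b_range Interval the exponential-move coefficient `b` is drawn from.
#' @return An object of class `assoa_params` (inherits `ss_params`).
#' @export
assoa_params <- function(n = 10L, t_m = 100L, G_c = 1.9, P_dp = 0.1, beta = 1.5,
                         dg_low = 0.5, dg_high = 1.11, p_threshold = 0.5,
                         p_fixed = NULL, a_fixed = NULL, d_fixed = NULL,
                         b_range = c(0, 1)) {
  p <- ss_params(n, t_m, G_c, P_dp, beta, dg_low, dg_high)
  if (p_threshold < 0 || p_threshold > 1) stop("`p_threshold` must lie in [0, 1]", call. = FALSE)
  p$p_threshold <- p_threshold
  p$p_fixed <- p_fixed
  p$a_fixed <- a_fixed
  p$d_fixed <- d_fixed
  p$b_range <- b_range
  class(p) <- c("assoa_params", "ss_params")
  p
}

#' Grey wolf optimizer parameters
#'
#' @inheritParams ss_params
#' @return An object of class `gwo_params`. The exploration coefficient `a`
#'   decays linearly from 2 at the first iteration to 0 at the last.
#' @export
gwo_params <- function(n = 10L, t_m = 100L) {
  if (n < 5) stop("`n` must be at least 5", call. = FALSE)
  if (t_m < 1) stop("`t_m` must be at least 1", call. = FALSE)
  structure(list(n = as.integer(n), t_m = as.integer(t_m)), class = "gwo_params")
}

#' Genetic algorithm parameters
#'
#' Generational GA with tournament selection, arithmetic crossover on
#' continuous spaces (single-point on binary-from-continuous spaces),
#' per-gene uniform mutation and elitism.
#'
#' @inheritParams ss_params
#' @param crossover Crossover probability.
#' @param mutation Per-gene mutation probability; `NULL` means `1/d`, resolved
#'   against the search space at run time.
#' @param tournament Tournament size.
#' @param elitism Number of best individuals copied unchanged each generation.
#' @return An object of class `ga_params`.
#' @export
ga_params <- function(n = 10L, t_m = 100L, crossover = 0.9, mutation = NULL,
                      tournament = 3L, elitism = 1L) {
  if (n < 5) stop("`n` must be at least 5", call. = FALSE)
  if (t_m < 1) stop("`t_m` must be at least 1", call. = FALSE)
  if (crossover < 0 || crossover > 1) stop("`crossover` must lie in [0, 1]", call. = FALSE)
  if (!is.null(mutation) && (mutation < 0 || mutation > 1)) {
    stop("`mutation` must lie in [0, 1]", call. = FALSE)
  }
  if (elitism >= n) stop("`elitism` must be below the population size", call. = FALSE)
  structure(list(n = as.integer(n), t_m = as.integer(t_m), crossover = crossover,
                 mutation = mutation, tournament = as.integer(tournament),
                 elitism = as.integer(elitism)), class = "ga_params")
}
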