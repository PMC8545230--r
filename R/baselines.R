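#' One iteration of the grey wolf optimizer
#'
#' Canonical GWO update: the three best agents (alpha, beta, delta) each
#' propose a candidate for every other agent via `X_l - A |C X_l - X|` with
#' `A = 2 a r1 - a`, `C = 2 r2` drawn per agent, leader and dimension; the new
#' position is the mean of the three candidates. The exploration coefficient
#' `a` decays linearly from 2 (first iteration) to 0 (last), so late
#' iterations collapse onto the leaders.
#'
#' @inheritParams ss_step
#' @param params A [gwo_params()].
#' @return The updated, re-evaluated population.
#' @export
gwo_step <- function(pop, params, space, objective, t) {
  check_evaluated(pop)
  if (pop$n < 3) stop("GWO needs at least 3 agents", call. = FALSE)
  a <- if (params$t_m > 1) 2 * (1 - (t - 1) / (params$t_m - 1)) else 0
  ord <- order(pop$fitness)
  leaders <- pop$positions[ord[1:3], , drop = FALSE]
  old <- pop$positions
  new <- old
  d <- space$dims
  for (i in seq_len(pop$n)) {
    cand <- matrix(0, 3, d)
    for (l in 1:3) {
      A <- 2 * a * stats::runif(d) - a
      C <- 2 * stats::runif(d)
      D <- abs(C * leaders[l, ] - old[i, ])
      cand[l, ] <- leaders[l, ] - A * D
    }
    new[i, ] <- colMeans(cand)
  }
  pop$positions <- clip_to_bounds(new, space)
  pop$velocities <- pop$positions - old
  evaluate_population(pop, objective)
}

#' One generation of the genetic algorithm
#'
#' Generational GA: tournament selection, arithmetic crossover on continuous
#' spaces (single-point on `"binary-from-continuous"` spaces), per-gene
#' uniform mutation within the bounds, and elitism copying the current best
#' individuals unchanged so the best fitness never worsens.
#'
#' @inheritParams ss_step
#' @param params A [ga_params()].
#' @return The updated, re-evaluated population.
#' @export
ga_step <- function(pop, params, space, objective, t) {
  check_evaluated(pop)
  if (params$elitism >= pop$n) stop("`elitism` must be below the population size", call. = FALSE)
  d <- space$dims
  pm <- if (is.null(params$mutation)) 1 / d else params$mutation
  old <- pop$positions
  ord <- order(pop$fitness)
  new <- matrix(NA_real_, pop$n, d)
  k <- params$elitism
  if (k > 0) new[seq_len(k), ] <- old[ord[seq_len(k)], , drop = FALSE]

  pick <- function() {
    contenders <- sample.int(pop$n, params$tournament, replace = TRUE)
    contenders[which.min(pop$fitness[contenders])]
  }
  i <- k + 1L
  while (i <= pop$n) {
    p1 <- old[pick(), ]
    p2 <- old[pick(), ]
    if (stats::runif(1) < params$crossover) {
      if (space$mode == "binary-from-continuous") {
        cut <- sample.int(d, 1L)
        c1 <- c(p1[seq_len(cut)], p2[seq_len(d)[-seq_len(cut)]])
        c2 <- c(p2[seq_len(cut)], p1[seq_len(d)[-seq_len(cut)]])
      } else {
        u <- stats::runif(1)
        c1 <- u * p1 + (1 - u) * p2
        c2 <- u * p2 + (1 - u) * p1
      }
    } else {
      c1 <- p1; c2 <- p2
    }
    for (child in list(c1, c2)) {
      if (i > pop$n) break
      mut <- stats::runif(d) < pm
      if (any(mut)) {
        child[mut] <- space$lower[mut] +
          stats::runif(sum(mut)) * (space$upper[mut] - space$lower[mut])
      }
      new[i, ] <- child
      i <- i + 1L
    }
  }
  pop$positions <- clip_to_bounds(new, space)
  pop$velocities <- pop$positions - old
  evaluate_population(pop, objective)
}
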