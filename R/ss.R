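#' Glide move toward a better agent
#'
#' The elementary squirrel-search displacement
#' `x + d_g * G_c * (target - x)`: the agent glides a random fraction of the
#' way toward (and typically past) a better food source. The caller clips the
#' result to the search-space bounds.
#'
#' @param x Current position.
#' @param target Position glided toward (hickory or acorn agent).
#' @param d_g Gliding distance (random scalar).
#' @param G_c Gliding constant, 1.9 by default in the algorithms.
#' @return The displaced position, same length as `x`.
#' @export
glide_move <- function(x, target, d_g, G_c) {
  if (length(x) != length(target)) stop("`x` and `target` must have equal length", call. = FALSE)
  x + d_g * G_c * (target - x)
}

# The three basic glide cases shared verbatim by the SS step and the
# p >= 0.5 branch of the ASSOA step. RNG draw order (fixed contract):
# per acorn agent in rank order: R1, then d_g or the d uniform coordinates;
# per n2_split agent: R2, then acorn choice + d_g, or coordinates;
# per n3_split agent: R3, then d_g or coordinates.
# All displacements use the iteration-start position snapshot.
move_cases_123 <- function(pop, roles, params, space) {
  old <- pop$positions
  new <- old
  trace <- rep(NA_character_, pop$n)
  ht <- old[roles$hickory, ]

  for (k in roles$acorn) {
    if (stats::runif(1) >= params$P_dp) {
      d_g <- stats::runif(1, params$dg_low, params$dg_high)
      new[k, ] <- glide_move(old[k, ], ht, d_g, params$G_c)
      trace[k] <- "case1"
    } else {
      new[k, ] <- uniform_position(space)
      trace[k] <- "random-location"
    }
  }
  for (i in roles$n2_split) {
    if (stats::runif(1) >= params$P_dp) {
      at <- old[roles$acorn[sample.int(3L, 1L)], ]
      d_g <- stats::runif(1, params$dg_low, params$dg_high)
      new[i, ] <- glide_move(old[i, ], at, d_g, params$G_c)
      trace[i] <- "case2"
    } else {
      new[i, ] <- uniform_position(space)
      trace[i] <- "random-location"
    }
  }
  for (i in roles$n3_split) {
    if (stats::runif(1) >= params$P_dp) {
      d_g <- stats::runif(1, params$dg_low, params$dg_high)
      new[i, ] <- glide_move(old[i, ], ht, d_g, params$G_c)
      trace[i] <- "case3"
    } else {
      new[i, ] <- uniform_position(space)
      trace[i] <- "random-location"
    }
  }
  list(positions = clip_to_bounds(new, space), trace = trace)
}

# seasonal stagnation check on the post-move positions; returns TRUE when the
# closest acorn-to-hickory distance has collapsed below the decaying threshold
seasonal_triggered <- function(positions, roles, t, t_m) {
  ht <- positions[roles$hickory, ]
  sc <- vapply(roles$acorn, function(k) sqrt(sum((positions[k, ] - ht)^2)), numeric(1))
  min(sc) < seasonal_minimum(t, t_m)
}

#' One iteration of the basic squirrel search algorithm
#'
#' Applies the three glide cases (acorn agents toward the hickory; one random
#' half of the normal agents toward a random acorn; the other half toward the
#' hickory), each replaced by a uniform random relocation with probability
#' `P_dp`. Afterwards the seasonal monitoring condition is checked and, when
#' triggered, every normal agent is relocated by a Lévy flight over the box:
#' `lower + Levy * (upper - lower)`. All positions are clipped to the bounds
#' and the whole population is re-evaluated.
#'
#' @param pop An evaluated `population`.
#' @param roles A `role_assignment` current for `pop`.
#' @param params An [ss_params()].
#' @param space The [search_space()].
#' @param objective The objective function (minimized).
#' @param t Current iteration, in `1:params$t_m`.
#' @return The updated, re-evaluated population; the per-agent move trace is
#'   attached as attribute `"trace"`.
#' @export
ss_step <- function(pop, roles, params, space, objective, t) {
  check_evaluated(pop)
  old <- pop$positions
  moved <- move_cases_123(pop, roles, params, space)
  new <- moved$positions
  trace <- moved$trace

  if (seasonal_triggered(new, roles, t, params$t_m)) {
    for (i in roles$normal) {
      step <- levy_sample(params$beta, space$dims)
      new[i, ] <- space$lower + step * (space$upper - space$lower)
      trace[i] <- "relocation-SS"
    }
    new <- clip_to_bounds(new, space)
  }

  pop$positions <- new
  pop <- evaluate_population(pop, objective)
  attr(pop, "trace") <- trace
  pop
}
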