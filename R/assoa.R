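#' Seasonal relocation of the advanced squirrel search
#'
#' Component-wise relocation of a normal agent around the hickory agent:
#' `x_ht + 2 r (x_ht - x_nt) (1 - ((x_ht + x_nt) / x_nt)^2)`.
#' A zero component of `x_nt` is replaced by `sign(x_nt) * 1e-10` (with
#' `sign(0)` taken as +1) so the ratio never divides by zero. The caller clips
#' the result to the search-space bounds.
#'
#' @param x_nt Normal-agent position.
#' @param x_ht Hickory (best) position, same length.
#' @param r Random scalar in \[0, 1\].
#' @return The relocated position.
#' @examples
#' relocate_assoa(1, 2, 0.5)  # -6
#' @export
relocate_assoa <- function(x_nt, x_ht, r) {
  if (length(x_nt) != length(x_ht)) stop("positions must have equal length", call. = FALSE)
  denom <- x_nt
  zero <- denom == 0
  if (any(zero)) denom[zero] <- ifelse(sign(x_nt[zero]) < 0, -1e-10, 1e-10)
  x_ht + 2 * r * ((x_ht - x_nt) * (1 - ((x_ht + x_nt) / denom)^2))
}

#' One iteration of the advanced squirrel search algorithm (ASSOA)
#'
#' A per-iteration draw `p` gates the move block: when `p >= p_threshold` the
#' three basic glide cases of [ss_step()] run unchanged. Otherwise only the
#' normal agents move, by one of three advanced cases decided by further
#' per-iteration draws:
#' \describe{
#'   \item{diagonal (case 4, when `P_a < a`)}{`x + V + c1 r (ht - x) + c2 r (at - x)`
#'     with `at` the nearest acorn agent;}
#'   \item{vertical/horizontal (case 5, when `P_d < d`)}{toward a random normal
#'     agent if that agent is fitter, else toward the hickory, each plus the
#'     velocity term;}
#'   \item{exponential (case 6, otherwise)}{`x + |x_rand - x| exp(b tau) cos(2 pi tau)`
#'     with normalized iteration `tau = t / t_m`.}
#' }
#' The velocity matrix enters cases 4-5 additively; velocities are initialized
#' to zero and carry no update rule, so the terms are structurally present but
#' inert (see the methods vignette for why a momentum-style update was
#' rejected). The seasonal stagnation check then relocates the normal agents
#' via [relocate_assoa()]. Positions are clipped and the population
#' re-evaluated.
#'
#' @inheritParams ss_step
#' @param params An [assoa_params()].
#' @return The updated, re-evaluated population with a `"trace"` attribute.
#' @export
assoa_step <- function(pop, roles, params, space, objective, t) {
  check_evaluated(pop)
  old <- pop$positions
  p <- if (!is.null(params$p_fixed)) params$p_fixed else stats::runif(1)

  if (p >= params$p_threshold) {
    moved <- move_cases_123(pop, roles, params, space)
    new <- moved$positions
    trace <- moved$trace
  } else {
    new <- old
    trace <- rep(NA_character_, pop$n)
    ht <- old[roles$hickory, ]
    P_a <- stats::runif(1)
    a <- if (!is.null(params$a_fixed)) params$a_fixed else stats::runif(1)
    if (P_a < a) {
      for (i in roles$normal) {
        at <- old[nearest_acorn(old, roles, i), ]
        c1 <- stats::runif(1); c2 <- stats::runif(1); r <- stats::runif(1)
        new[i, ] <- old[i, ] + pop$velocities[i, ] +
          c1 * r * (ht - old[i, ]) + c2 * r * (at - old[i, ])
        trace[i] <- "case4"
      }
    } else {
      P_d <- stats::runif(1)
      d_thr <- if (!is.null(params$d_fixed)) params$d_fixed else stats::runif(1)
      for (i in roles$normal) {
        j <- roles$normal[sample.int(length(roles$normal), 1L)]
        if (P_d < d_thr) {
          if (pop$fitness[j] < pop$fitness[i]) {
            c3 <- stats::runif(1); r <- stats::runif(1)
            new[i, ] <- old[i, ] + pop$velocities[i, ] + c3 * r * (old[j, ] - old[i, ])
          } else {
            c1 <- stats::runif(1); r <- stats::runif(1)
            new[i, ] <- old[i, ] + pop$velocities[i, ] + c1 * r * (ht - old[i, ])
          }
          trace[i] <- "case5"
        } else {
          b <- stats::runif(1, params$b_range[1], params$b_range[2])
          tau <- t / params$t_m
          new[i, ] <- old[i, ] + abs(old[j, ] - old[i, ]) * exp(b * tau) * cos(2 * pi * tau)
          trace[i] <- "case6"
        }
      }
    }
    new <- clip_to_bounds(new, space)
  }

  if (seasonal_triggered(new, roles, t, params$t_m)) {
    ht_now <- new[roles$hickory, ]
    for (i in roles$normal) {
      r <- stats::runif(1)
      new[i, ] <- relocate_assoa(new[i, ], ht_now, r)
      trace[i] <- "relocation-ASSOA"
    }
    new <- clip_to_bounds(new, space)
  }

  pop$positions <- new
  pop <- evaluate_population(pop, objective)
  attr(pop, "trace") <- trace
  pop
}

# nearest acorn agent (Euclidean) to agent i; ties -> first in rank order
nearest_acorn <- function(positions, roles, i) {
  d2 <- vapply(roles$acorn,
               function(k) sum((positions[k, ] - positions[i, ])^2), numeric(1))
  roles$acorn[which.min(d2)]
}
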