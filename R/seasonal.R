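#' Seasonal monitoring constant
#'
#' Euclidean distance from each of the three acorn agents to the hickory
#' agent. When every acorn sits essentially on top of the hickory the
#' population has stagnated and the seasonal relocation of normal agents is
#' triggered (compare against [seasonal_minimum()]).
#'
#' @param pop A `population`.
#' @param roles A `role_assignment` current for `pop`.
#' @return Numeric vector of length 3, one distance per acorn agent.
#' @export
seasonal_constant <- function(pop, roles) {
  stopifnot(inherits(pop, "population"), inherits(roles, "role_assignment"))
  ht <- pop$positions[roles$hickory, ]
  vapply(roles$acorn, function(k) sqrt(sum((pop$positions[k, ] - ht)^2)), numeric(1))
}

#' Seasonal trigger threshold
#'
#' The stagnation threshold decays with iteration as
#' `1e-6 / 365^(2.5 * t / t_m)`: early iterations tolerate tight clustering,
#' late iterations essentially never trigger, shifting the balance from
#' exploration toward exploitation.
#'
#' @param t Current iteration (1-based).
#' @param t_m Maximum number of iterations, at least 1.
#' @return A single numeric threshold.
#' @export
seasonal_minimum <- function(t, t_m) {
  if (length(t_m) != 1L || !is.finite(t_m) || t_m < 1) {
    stop("`t_m` must be a positive integer", call. = FALSE)
  }
  1e-6 / 365^(2.5 * t / t_m)
}
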