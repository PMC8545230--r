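#' Initialize a flying-squirrel population
#'
#' Positions are drawn i.i.d. uniform per dimension within the box bounds;
#' velocities start at zero; fitness is an NA sentinel until
#' [evaluate_population()] is called (any role assignment on unevaluated
#' fitness errors loudly rather than reading stale values).
#'
#' @param space A [search_space()].
#' @param n Population size; at least 5 (one hickory, three acorn, at least one
#'   normal agent are required by the role structure).
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   first. Inside [run_optimizer()] the run seed is set once and this is left
#'   `NULL`.
#' @return An object of class `population`: list with `positions` (n x d),
#'   `velocities` (n x d), `fitness` (length n), `n`, and an evaluation
#'   counter environment.
#' @export
init_population <- function(space, n, seed = NULL) {
  stopifnot(inherits(space, "search_space"))
  if (n < 5) {
    stop("population size must be at least 5 (1 hickory + 3 acorn + >=1 normal agent)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  d <- space$dims
  pos <- matrix(stats::runif(n * d), n, d)
  pos <- sweep(sweep(pos, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  structure(list(
    positions = pos,
    velocities = matrix(0, n, d),
    fitness = rep(NA_real_, n),
    n = n,
    counter = new.env(parent = emptyenv())
  ), class = "population")
}

#' Evaluate the objective for every agent
#'
#' @param pop A `population`.
#' @param objective Function mapping a numeric vector of length `d` to a
#'   single finite numeric value (minimized).
#' @return The population with `fitness[i] = objective(positions[i, ])`; the
#'   evaluation counter is incremented by `n`.
#' @export
evaluate_population <- function(pop, objective) {
  stopifnot(inherits(pop, "population"))
  if (any(!is.finite(pop$positions))) stop("positions contain non-finite values", call. = FALSE)
  f <- vapply(seq_len(pop$n), function(i) objective(pop$positions[i, ]), numeric(1))
  bad <- which(!is.finite(f))
  if (length(bad)) {
    stop(sprintf("objective returned a non-finite value for agent %d", bad[1]), call. = FALSE)
  }
  pop$fitness <- f
  bump_evals(pop, pop$n)
  pop
}

bump_evals <- function(pop, by) {
  cur <- get0("n_evals", envir = pop$counter, ifnotfound = 0L)
  assign("n_evals", cur + as.integer(by), envir = pop$counter)
  invisible(NULL)
}

#' @rdname evaluate_population
#' @export
evaluation_count <- function(pop) {
  get0("n_evals", envir = pop$counter, ifnotfound = 0L)
}

check_evaluated <- function(pop) {
  if (anyNA(pop$fitness)) {
    stop("population fitness has not been evaluated; call evaluate_population() first",
         call. = FALSE)
  }
}

#' Assign hickory / acorn / normal roles by sorted fitness
#'
#' Minimization convention: the hickory agent is the current best (lowest
#' fitness), the three acorn agents are ranks 2-4, all remaining agents are
#' normal. Ties are broken by lower agent index (stable sort). The normal
#' agents are re-partitioned uniformly at random into two sets each call: one
#' glides toward a random acorn tree, the other toward the hickory tree.
#'
#' @param pop An evaluated `population` with at least 5 agents.
#' @return An object of class `role_assignment`: `hickory` (index), `acorn`
#'   (3 indices in rank order), `normal`, and the random split `n2_split` /
#'   `n3_split` of the normal agents.
#' @export
assign_roles <- function(pop) {
  stopifnot(inherits(pop, "population"))
  if (pop$n < 5) stop("need at least 5 agents to assign roles", call. = FALSE)
  check_evaluated(pop)
  ord <- order(pop$fitness)        # stable: ties broken by lower index
  normal <- ord[5:pop$n]
  # uniform random partition of the normal agents into the two glide groups
  toward_acorn <- stats::runif(length(normal)) < 0.5
  structure(list(
    hickory = ord[1],
    acorn = ord[2:4],
    normal = normal,
    n2_split = normal[toward_acorn],
    n3_split = normal[!toward_acorn]
  ), class = "role_assignment")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d agents in %d dims; fitness %s; %d evaluations\n",
              x$n, ncol(x$positions),
              if (anyNA(x$fitness)) "not evaluated" else
                sprintf("best %.6g", min(x$fitness)),
              evaluation_count(x)))
  invisible(x)
}
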