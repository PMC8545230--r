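# Registry of optimizers runnable through run_optimizer(). Each entry knows
# how to build default parameters for a space and how to advance one iteration.
the_registry <- new.env(parent = emptyenv())

register_algorithm <- function(name, default_params, step) {
  assign(name, list(default_params = default_params, step = step),
         envir = the_registry)
  invisible(name)
}

#' Names of the registered optimizers
#' @return Character vector, e.g. `c("assoa", "ga", "gwo", "ss")`.
#' @export
registered_algorithms <- function() sort(ls(the_registry))

# built-ins; ss and assoa re-assign roles every iteration (which consumes one
# uniform draw per normal agent for the glide-group partition)
local({
  register_algorithm("ss",
    default_params = function(space) ss_params(),
    step = function(pop, params, space, objective, t) {
      roles <- assign_roles(pop)
      ss_step(pop, roles, params, space, objective, t)
    })
  register_algorithm("assoa",
    default_params = function(space) assoa_params(),
    step = function(pop, params, space, objective, t) {
      roles <- assign_roles(pop)
      assoa_step(pop, roles, params, space, objective, t)
    })
  register_algorithm("gwo",
    default_params = function(space) gwo_params(),
    step = gwo_step)
  register_algorithm("ga",
    default_params = function(space) ga_params(),
    step = ga_step)
})

#' Run a registered optimizer on an objective
#'
#' Drives any registered algorithm for `params$t_m` iterations from a fresh
#' uniform population, recording the best-so-far fitness after each iteration.
#' The whole run consumes a single RNG stream seeded once from `seed`, so an
#' identical `(algorithm, space, objective, params, seed)` tuple reproduces
#' the result bit-identically.
#'
#' @param algorithm Name in [registered_algorithms()].
#' @param space A [search_space()].
#' @param objective A function, or the name of a built-in (see
#'   [get_objective()]). Minimized; negate for maximization.
#' @param params Algorithm parameter object; `NULL` uses that algorithm's
#'   defaults.
#' @param seed Integer seed for the run.
#' @param trace Logical; record the per-agent move trace of the squirrel
#'   algorithms (`$trace`: iteration, agent, case).
#' @return An `optimizer_result`: `best_position`, `best_fitness`, the
#'   non-increasing best-so-far `curve`, `seed`, `evaluations` and the echoed
#'   configuration.
#' @examples
#' r <- run_optimizer("assoa", search_space(5, -5, 5), "sphere",
#'                    assoa_params(n = 10, t_m = 25), seed = 1)
#' r$best_fitness
#' @export
run_optimizer <- function(algorithm, space, objective, params = NULL, seed = 1L,
                          trace = FALSE) {
  if (!is.character(algorithm) || !algorithm %in% registered_algorithms()) {
    stop(sprintf("unknown algorithm '%s'; registered: %s",
                 as.character(algorithm)[1],
                 paste(registered_algorithms(), collapse = ", ")), call. = FALSE)
  }
  entry <- get(algorithm, envir = the_registry)
  objective <- get_objective(objective)
  if (is.null(params)) params <- entry$default_params(space)
  if (is.null(params$n) || is.null(params$t_m)) {
    stop("`params` must carry the population size `n` and iteration budget `t_m`",
         call. = FALSE)
  }

  set.seed(as.integer(seed))
  pop <- init_population(space, params$n)
  pop <- evaluate_population(pop, objective)
  best_i <- which.min(pop$fitness)
  best_fit <- pop$fitness[best_i]
  best_pos <- pop$positions[best_i, ]

  t_m <- params$t_m
  curve <- numeric(t_m)
  traces <- if (trace) vector("list", t_m) else NULL
  for (t in seq_len(t_m)) {
    pop <- entry$step(pop, params, space, objective, t)
    it_best <- which.min(pop$fitness)
    if (pop$fitness[it_best] < best_fit) {
      best_fit <- pop$fitness[it_best]
      best_pos <- pop$positions[it_best, ]
    }
    curve[t] <- best_fit
    if (trace) {
      tr <- attr(pop, "trace")
      if (!is.null(tr)) {
        moved <- which(!is.na(tr))
        traces[[t]] <- data.frame(iteration = t, agent = moved, case = tr[moved])
      }
    }
  }

  structure(list(
    algorithm = algorithm,
    best_position = best_pos,
    best_fitness = best_fit,
    curve = curve,
    seed = as.integer(seed),
    evaluations = evaluation_count(pop),
    params = params,
    trace = if (trace) do.call(rbind, traces) else NULL
  ), class = "optimizer_result")
}

#' @export
print.optimizer_result <- function(x, ...) {
  cat(sprintf("<optimizer_result> %s: best fitness %.6g after %d iterations (%d evaluations, seed %d)\n",
              x$algorithm, x$best_fitness, length(x$curve), x$evaluations, x$seed))
  invisible(x)
}

#' Write an optimizer result to disk
#'
#' Writes the convergence curve as CSV (`iteration`, `best_fitness`) and a JSON
#' run summary (algorithm, seed, evaluations, best position, parameter echo).
#'
#' @param result An `optimizer_result`.
#' @param curve_path,summary_path Output file paths (`NULL` skips that file).
#' @return `result`, invisibly.
#' @export
write_result <- function(result, curve_path = NULL, summary_path = NULL) {
  stopifnot(inherits(result, "optimizer_result"))
  if (!is.null(curve_path)) {
    utils::write.csv(data.frame(iteration = seq_along(result$curve),
                                best_fitness = result$curve),
                     curve_path, row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    params <- result$params[!vapply(result$params, is.null, logical(1))]
    class(params) <- NULL
    jsonlite::write_json(list(
      algorithm = result$algorithm,
      seed = result$seed,
      evaluations = result$evaluations,
      best_fitness = result$best_fitness,
      best_position = result$best_position,
      params = params
    ), summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
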