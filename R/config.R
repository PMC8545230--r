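# known configuration keys and their defaults (NULL = no default, optional)
config_schema <- function() {
  list(
    task = NULL,                 # optimize | select-features | train-classifier | compare | simulate-data
    algorithm = "assoa",
    algorithms = c("assoa", "ss"),
    objective = "sphere",
    dims = 10L,
    lower = -5, upper = 5,
    data = NULL,
    label_column = "label",
    output = ".",
    seed = 1L,
    agents = 10L,
    iterations = 100L,
    runs = 30L,
    h1 = 0.99,
    classifier = "knn",
    k = 5L,
    hidden = NULL,
    kind = "planted",
    n_samples = 150L,
    features = 10L,
    k_informative = 2L,
    delta = 3,
    margin = 1,
    G_c = 1.9,
    P_dp = 0.1,
    beta = 1.5,
    dg_low = 0.5,
    dg_high = 1.11,
    crossover = 0.9,
    mutation = NULL,
    tournament = 3L,
    elitism = 1L,
    split = c(0.6, 0.2, 0.2)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, rejects unknown keys (with a
#' closest-match suggestion), fills defaults (`G_c = 1.9`, `P_dp = 0.1`,
#' `beta = 1.5`, `h1 = 0.99`, 60/20/20 split, ...), and validates the values
#' before any computation runs.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a named list.
#' @return An object of class `run_config` (a validated named list with all
#'   defaults materialized).
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    hint <- vapply(unknown, function(k) {
      near <- agrep(k, names(schema), max.distance = 2, value = TRUE)
      if (length(near)) sprintf(" (did you mean '%s'?)", near[1]) else ""
    }, character(1))
    stop(sprintf("unknown configuration key(s): %s",
                 paste0("'", unknown, "'", hint, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(schema, raw, keep.null = TRUE)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  tasks <- c("optimize", "select-features", "train-classifier", "compare", "simulate-data")
  if (!is.null(cfg$task) && !cfg$task %in% tasks) {
    stop(sprintf("key 'task' must be one of: %s", paste(tasks, collapse = ", ")),
         call. = FALSE)
  }
  num_keys <- c("h1", "G_c", "P_dp", "beta", "seed", "agents", "iterations", "runs")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1) {
      stop(sprintf("key '%s' must be a single number", k), call. = FALSE)
    }
  }
  if (cfg$h1 < 0 || cfg$h1 > 1) stop("key 'h1' must lie in [0, 1]", call. = FALSE)
  if (cfg$agents < 5) stop("key 'agents' must be at least 5", call. = FALSE)
  if (cfg$iterations < 1) stop("key 'iterations' must be at least 1", call. = FALSE)
  if (length(cfg$split) != 3 || abs(sum(cfg$split) - 1) > 1e-8) {
    stop("key 'split' must be three proportions summing to 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Write the configuration echo
#'
#' Every run writes the fully materialized configuration back out so the run
#' is reproducible from its output directory alone; the echo round-trips
#' through [load_config()] to an identical configuration.
#'
#' @param cfg A `run_config`.
#' @param dir Output directory.
#' @return The echo path, invisibly.
#' @export
write_config_echo <- function(cfg, dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "config_echo.yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' Build an algorithm's parameter object from a run configuration
#'
#' Maps the flat configuration keys (`agents`, `iterations`, `G_c`, `P_dp`,
#' `beta`, GA operators, ...) onto the parameter constructor of the named
#' algorithm.
#'
#' @param cfg A `run_config` from [load_config()].
#' @param algorithm One of the registered algorithm names.
#' @return An `ss_params`, `assoa_params`, `gwo_params` or `ga_params` object.
#' @export
params_from_config <- function(cfg, algorithm) {
  switch(algorithm,
    ss = ss_params(n = cfg$agents, t_m = cfg$iterations, G_c = cfg$G_c,
                   P_dp = cfg$P_dp, beta = cfg$beta,
                   dg_low = cfg$dg_low, dg_high = cfg$dg_high),
    assoa = assoa_params(n = cfg$agents, t_m = cfg$iterations, G_c = cfg$G_c,
                         P_dp = cfg$P_dp, beta = cfg$beta,
                         dg_low = cfg$dg_low, dg_high = cfg$dg_high),
    gwo = gwo_params(n = cfg$agents, t_m = cfg$iterations),
    ga = ga_params(n = cfg$agents, t_m = cfg$iterations, crossover = cfg$crossover,
                   mutation = cfg$mutation, tournament = cfg$tournament,
                   elitism = cfg$elitism),
    stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE)
  )
}
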