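#' Built-in benchmark objectives
#'
#' Standard continuous test functions, all minimized with global minimum 0 at
#' the origin (sphere, rastrigin) or at the all-ones point (rosenbrock).
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"rosenbrock"`, or a function
#'   (returned unchanged).
#' @return A function mapping a numeric vector to a single numeric.
#' @examples
#' get_objective("sphere")(c(1, 2))  # 5
#' @export
get_objective <- function(name) {
  if (is.function(name)) return(name)
  switch(name,
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    rosenbrock = function(x) {
      n <- length(x)
      sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
    },
    stop(sprintf("unknown objective '%s'; built-ins: sphere, rastrigin, rosenbrock", name),
         call. = FALSE)
  )
}
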