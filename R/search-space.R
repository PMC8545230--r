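#' Define a box-bounded search space
#'
#' A search space is a hyper-rectangle `[lower, upper]` in `dims` dimensions.
#' All optimizers in the package clip candidate positions to these bounds after
#' every update. In `"binary-from-continuous"` mode the continuous positions are
#' interpreted through the sigmoid transfer function (see [binarize()]) by the
#' objective; the search itself is still continuous.
#'
#' @param dims Positive integer, number of dimensions.
#' @param lower,upper Numeric bounds; scalars are recycled to length `dims`.
#'   Must satisfy `lower[j] < upper[j]` for every `j`.
#' @param mode `"continuous"` (default) or `"binary-from-continuous"`.
#' @return An object of class `search_space`.
#' @examples
#' search_space(10, -5, 5)
#' @export
search_space <- function(dims, lower, upper, mode = c("continuous", "binary-from-continuous")) {
  mode <- match.arg(mode)
  if (length(dims) != 1L || !is.finite(dims) || dims < 1 || dims != round(dims)) {
    stop("`dims` must be a single positive integer", call. = FALSE)
  }
  dims <- as.integer(dims)
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("`lower[j]` must be strictly below `upper[j]` for every dimension", call. = FALSE)
  }
  structure(list(dims = dims, lower = lower, upper = upper, mode = mode),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> %d dims, mode '%s'\n", x$dims, x$mode))
  cat("  lower:", paste(signif(utils::head(x$lower, 6), 4), collapse = " "),
      if (x$dims > 6) "...\n" else "\n")
  cat("  upper:", paste(signif(utils::head(x$upper, 6), 4), collapse = " "),
      if (x$dims > 6) "...\n" else "\n")
  invisible(x)
}

# clip a position matrix (n x d) or vector to the box
clip_to_bounds <- function(x, space) {
  if (is.matrix(x)) {
    x <- pmin(pmax(x, matrix(space$lower, nrow(x), space$dims, byrow = TRUE)),
              matrix(space$upper, nrow(x), space$dims, byrow = TRUE))
  } else {
    x <- pmin(pmax(x, space$lower), space$upper)
  }
  x
}

uniform_position <- function(space) {
  space$lower + stats::runif(space$dims) * (space$upper - space$lower)
}
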