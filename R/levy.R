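#' Lévy flight scale factor
#'
#' Closed form for the scale sigma of the Lévy step used in exploratory
#' relocation:
#' \deqn{\sigma = \left(\frac{\Gamma(1+\beta)\sin(\pi\beta/2)}
#'   {\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}}\right)^{1/\beta}}
#'
#' @param beta Stability exponent in (0, 2]; the squirrel search algorithms use
#'   1.5.
#' @return The scale sigma as a single numeric.
#' @examples
#' levy_sigma(1.5)
#' levy_sigma(1.0)  # exactly 1
#' @export
levy_sigma <- function(beta) {
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0 || beta > 2) {
    stop("`beta` must be a single value in (0, 2]", call. = FALSE)
  }
  num <- gamma(1 + beta) * sin(pi * beta / 2)
  den <- gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)
  (num / den)^(1 / beta)
}

#' Draw a Lévy-flight step vector
#'
#' Each component is `0.01 * r_a * sigma / |r_b|^(1/beta)` with `r_a`, `r_b`
#' uniform on (0, 1) drawn independently per component; a zero `r_b` draw is
#' redrawn so the step is always finite. The distribution is heavy-tailed.
#'
#' @param beta Stability exponent in (0, 2].
#' @param dims Number of components.
#' @param r_a,r_b Optional fixed values overriding the random draws
#'   (recycled to `dims`); used for deterministic checks.
#' @return Numeric vector of length `dims`.
#' @export
levy_sample <- function(beta, dims, r_a = NULL, r_b = NULL) {
  sigma <- levy_sigma(beta)
  if (is.null(r_a)) r_a <- stats::runif(dims)
  if (is.null(r_b)) {
    r_b <- stats::runif(dims)
    while (any(r_b == 0)) r_b[r_b == 0] <- stats::runif(sum(r_b == 0))
  }
  r_a <- rep_len(r_a, dims)
  r_b <- rep_len(r_b, dims)
  if (any(r_b == 0)) stop("`r_b` must be nonzero", call. = FALSE)
  0.01 * r_a * sigma / abs(r_b)^(1 / beta)
}
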