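#' Irwin-Hall distribution for the sum of two standard uniforms
#'
#' Density, distribution function, quantile function and the two-sided
#' tail transform for the sum \eqn{x = q_O + q_R} of two independent
#' Uniform(0,1) variables.  This triangular distribution is the null
#' reference for the hybrid method's combined probability statistic.
#'
#' Closed forms on the support \eqn{[0, 2]}:
#' \deqn{F(x) = x^2/2 \ (x \le 1), \qquad F(x) = -x^2/2 + 2x - 1 \ (x > 1)}
#' The two-sided transform folds both tails,
#' \eqn{G(x) = 2\min\{F(x), 1-F(x)\}}, so that \eqn{G(1) = 1} and small
#' values of G indicate an x that is extreme in either direction.
#'
#' @param x,q Quantile(s); clipped into \eqn{[0, 2]}.
#' @param p Probability (or probabilities) in \eqn{[0, 1]}.
#' @return Numeric vector of densities, probabilities or quantiles.
#' @examples
#' qirwinhall(c(.025, .05))  # 0.224, 0.316
#' @name irwinhall
NULL

#' @rdname irwinhall
#' @export
dirwinhall <- function(x) {
  x <- pmin(pmax(x, 0), 2)
  ifelse(x <= 1, x, 2 - x)
}

#' @rdname irwinhall
#' @export
pirwinhall <- function(q) {
  q <- pmin(pmax(q, 0), 2)
  ifelse(q <= 1, q^2 / 2, -q^2 / 2 + 2 * q - 1)
}

#' @rdname irwinhall
#' @export
qirwinhall <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p must lie in [0, 1]")
  ifelse(p <= 0.5, sqrt(2 * p), 2 - sqrt(2 * (1 - p)))
}

#' @rdname irwinhall
#' @export
irwinhall_two_tailed <- function(x) {
  x <- pmin(pmax(x, 0), 2)
  ifelse(x <= 1, x^2, (x - 2)^2)
}
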