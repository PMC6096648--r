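#' Small-sample correction factor for standardized mean differences
#'
#' Hedges' correction \eqn{J = 1 - 3/(4\,df - 1)}, applied to Cohen's d to
#' remove its small-sample bias.  \eqn{J} is monotone increasing in the
#' degrees of freedom and tends to 1, so Hedges' g tends to d.
#'
#' @param df Degrees of freedom of the t statistic (positive).
#' @return The correction factor, a value in (0, 1).
#' @export
hedges_j <- function(df) {
  if (any(df <= 0)) stop("degrees of freedom must be positive")
  1 - 3 / (4 * df - 1)
}

new_effect_estimate <- function(metric, y, variance, design,
                                df = NA_real_, t_obs = NA_real_,
                                correction_J = NA_real_,
                                n1 = NA_integer_, n2 = NA_integer_,
                                n = NA_integer_) {
  stopifnot(variance > 0)
  structure(
    list(metric = metric, y = y, variance = variance, design = design,
         df = df, t_obs = t_obs, correction_J = correction_J,
         n1 = n1, n2 = n2, n = n),
    class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 4, ...) {
  lab <- switch(x$metric, hedges_g = "Hedges' g", fisher_z = "Fisher z")
  cat(lab, "effect estimate (", x$design, ")\n", sep = " ")
  cat("  y =", format(x$y, digits = digits),
      "  variance =", format(x$variance, digits = digits),
      "  se =", format(sqrt(x$variance), digits = digits), "\n")
  if (!is.na(x$df))
    cat("  t =", format(x$t_obs, digits = digits),
        " df =", x$df, " J =", format(x$correction_J, digits = digits), "\n")
  invisible(x)
}

#' Hedges' g from a two-sample t statistic
#'
#' Converts an independent two-group t statistic to Hedges' g on the
#' standardized-mean-difference scale: \eqn{g = J \, t \sqrt{1/n_1 + 1/n_2}}
#' with \eqn{df = n_1 + n_2 - 2}, together with its unbiased sampling
#' variance (see [g_variance()]).
#'
#' @param t Observed t statistic.
#' @param n1,n2 Per-group sample sizes (at least 2 each).
#' @return An object of class `"effect_estimate"` with metric `"hedges_g"`.
#' @examples
#' g_from_t(2.211, 40, 40)  # g = 0.490
#' @export
g_from_t <- function(t, n1, n2) {
  check_count(n1, 2, "n1"); check_count(n2, 2, "n2")
  stopifnot(is.finite(t))
  df <- n1 + n2 - 2
  J <- hedges_j(df)
  scale <- sqrt(1 / n1 + 1 / n2)
  g <- J * t * scale
  new_effect_estimate("hedges_g", g, g_variance(g, n1, n2),
                      design = "two_sample_means",
                      df = df, t_obs = t, correction_J = J,
                      n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Hedges' g from group means and standard deviations
#'
#' Derives the two-sample t statistic from summary data, using the pooled
#' standard deviation, and delegates to [g_from_t()].
#'
#' @param m1,m2 Group means.
#' @param sd1,sd2 Group standard deviations (positive).
#' @param n1,n2 Group sample sizes (at least 2 each).
#' @return An object of class `"effect_estimate"`.
#' @export
g_from_means <- function(m1, m2, sd1, sd2, n1, n2) {
  stopifnot(sd1 > 0, sd2 > 0)
  check_count(n1, 2, "n1"); check_count(n2, 2, "n2")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  t <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  g_from_t(t, n1, n2)
}

#' Unbiased sampling variance of Hedges' g (two-sample design)
#'
#' \deqn{\hat\sigma^2 = \frac{1}{n_1} + \frac{1}{n_2} +
#'   \left[1 - \frac{m-2}{m J^2}\right] g^2, \quad m = n_1 + n_2 - 2.}
#' The reciprocal is the inverse-variance weight used in fixed-effect
#' meta-analysis.  At g = 0 this reduces to \eqn{1/n_1 + 1/n_2}; the
#' g-dependent term is non-negative.
#'
#' @param g Hedges' g value.
#' @param n1,n2 Group sample sizes (at least 2 each).
#' @return The sampling variance, a positive scalar.
#' @examples
#' 1 / g_variance(0.490, 40, 40)  # weight 19.390
#' @export
g_variance <- function(g, n1, n2) {
  check_count(n1, 2, "n1"); check_count(n2, 2, "n2")
  m <- n1 + n2 - 2
  J <- hedges_j(m)
  1 / n1 + 1 / n2 + (1 - (m - 2) / (m * J^2)) * g^2
}

#' Hedges' g from a one-sample t statistic
#'
#' One-group analogue of [g_from_t()]: \eqn{g = J \, t / \sqrt{n}} with
#' \eqn{df = n - 1} and variance
#' \eqn{1/n + [1 - (n-3)/((n-1) J^2)] g^2}, the symmetric counterpart of the
#' two-sample unbiased estimator.
#'
#' @param t Observed one-sample t statistic.
#' @param n Sample size (at least 2).
#' @return An object of class `"effect_estimate"`.
#' @export
one_sample_g_from_t <- function(t, n) {
  check_count(n, 2, "n")
  stopifnot(is.finite(t))
  df <- n - 1
  J <- hedges_j(df)
  g <- J * t / sqrt(n)
  v <- 1 / n + (1 - (n - 3) / ((n - 1) * J^2)) * g^2
  new_effect_estimate("hedges_g", g, v, design = "one_sample_mean",
                      df = df, t_obs = t, correction_J = J,
                      n = as.integer(n))
}

#' Fisher z transform of a correlation
#'
#' \eqn{z = \mathrm{atanh}(r)} with sampling variance \eqn{1/(n-3)},
#' independent of r.  Results are back-transformed with `tanh` for reporting
#' on the correlation scale.
#'
#' @param r Observed correlation, strictly inside (-1, 1).
#' @param n Sample size (at least 4, so that n - 3 > 0).
#' @return An object of class `"effect_estimate"` with metric `"fisher_z"`.
#' @export
z_from_r <- function(r, n) {
  if (!is.finite(r) || abs(r) >= 1)
    stop("r must lie strictly between -1 and 1")
  check_count(n, 4, "n")
  new_effect_estimate("fisher_z", atanh(r), 1 / (n - 3),
                      design = "correlation", n = as.integer(n))
}

#' Back-transform an effect value to its reporting scale
#'
#' Fisher z values map back to correlations via `tanh`; Hedges' g is already
#' on its reporting scale and is returned unchanged.
#'
#' @param y Effect value(s) on the analysis scale.
#' @param metric Either `"hedges_g"` or `"fisher_z"`.
#' @return Numeric vector on the reporting scale.
#' @export
report_scale <- function(y, metric = c("hedges_g", "fisher_z")) {
  metric <- match.arg(metric)
  if (metric == "fisher_z") tanh(y) else y
}

check_count <- function(x, minimum, name) {
  if (length(x) != 1 || !is.finite(x) || x < minimum || x != round(x))
    stop(sprintf("%s must be an integer >= %d", name, minimum), call. = FALSE)
  invisible(x)
}
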