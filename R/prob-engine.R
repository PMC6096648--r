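#' Significance rule that selected the original study
#'
#' Describes the selection filter assumed for the original study: a
#' two-tailed test at level `alpha` of which only results in the expected
#' direction count, so the effective one-tailed selection level is
#' `alpha / 2` (.025 by default, common practice in psychology).
#'
#' @param alpha Two-tailed significance level of the original study's test,
#'   in (0, 1).  Default .05.
#' @param direction Expected direction of the effect.  With `"negative"`,
#'   both studies' effects are mirrored before analysis and results are
#'   mirrored back.
#' @return An object of class `"significance_rule"`.
#' @export
significance_rule <- function(alpha = 0.05,
                              direction = c("positive", "negative")) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  structure(list(alpha = alpha,
                 one_tailed_alpha = alpha / 2,
                 direction = match.arg(direction)),
            class = "significance_rule")
}

# --- accurate noncentral-t log survival function -------------------------
#
# stats::pt()'s noncentral algorithm carries an absolute error of ~1e-12,
# which destroys the tail *ratio* q_O when both tails are tiny (hypothesized
# effects far below the observations) -- precisely the region the hybrid CI
# lower bound lives in.  We therefore compute log P(T > t; df, ncp) by
# Gauss-Legendre quadrature over the chi mixing distribution,
#   T = (Z + ncp) / (S / sqrt(df)),  S ~ chi_df,
#   P(T > t) = E_S[ Phi_bar(t S / sqrt(df) - ncp) ],
# accumulated in log space, which keeps full relative accuracy.

gauss_legendre_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(gauss_legendre_cache[[key]])) return(gauss_legendre_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)                     # Jacobi matrix off-diagonal
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1)] <- b
  Jm[cbind(i + 1, i)] <- b
  e <- eigen(Jm, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  ord <- order(nodes)
  out <- list(nodes = nodes[ord], weights = weights[ord])
  gauss_legendre_cache[[key]] <- out
  out
}

log_sum_exp <- function(m) {
  # column-wise log-sum-exp of a matrix
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx))))
}

#' Log upper-tail probability of the noncentral t distribution
#'
#' Computes \eqn{\log P(T > t)} for \eqn{T \sim t(df, ncp)} with full
#' relative accuracy in the far tails, where `stats::pt()`'s noncentral
#' algorithm (absolute error about 1e-12) is unusable.  Used for the
#' conditional-probability ratios of the t backend.
#'
#' @param t Quantile (scalar).
#' @param df Degrees of freedom (scalar, at least 1).
#' @param ncp Noncentrality parameter; may be a vector.
#' @param nodes Number of Gauss-Legendre nodes for the chi mixture.
#' @return `log P(T > t; df, ncp)`, same length as `ncp`.
#' @export
log_nct_sf <- function(t, df, ncp, nodes = 400) {
  stopifnot(length(t) == 1, length(df) == 1, df >= 1)
  gl <- gauss_legendre(nodes)
  lo <- max(0, sqrt(df) - 12)
  hi <- sqrt(df) + 12
  s <- (gl$nodes + 1) / 2 * (hi - lo) + lo       # chi_df scale
  log_chi <- log(2) + (df - 1) * log(s) - s^2 / 2 -
    (df / 2) * log(2) - lgamma(df / 2)
  log_w <- log(gl$weights * (hi - lo) / 2)
  # matrix: nodes x length(ncp)
  arg <- outer(t * s / sqrt(df), ncp, `-`)
  log_tail <- pnorm(arg, lower.tail = FALSE, log.p = TRUE)
  log_sum_exp(log_tail + (log_chi + log_w))
}

ncp_factor <- function(est) {
  # multiply (theta_g / J) by this to get the noncentrality parameter
  switch(est$design,
         two_sample_means = sqrt(est$n1 * est$n2 / (est$n1 + est$n2)),
         one_sample_mean  = sqrt(est$n),
         stop("t backend requires a mean-difference design"))
}

#' Critical value of the original study's selection test
#'
#' The smallest effect (normal backend) or t value (t backend) that would
#' have been statistically significant in the expected direction under the
#' rule that selected the original study.  Independent of the hypothesized
#' true effect.
#'
#' @param original An [effect_estimate][g_from_t] for the original study.
#' @param rule A [significance_rule()].
#' @param backend `"normal"` (threshold on the effect scale) or `"nct"`
#'   (threshold on the t scale).
#' @return A positive scalar threshold.
#' @export
critical_value <- function(original, rule = significance_rule(),
                           backend = c("normal", "nct")) {
  backend <- match.arg(backend)
  if (backend == "normal")
    qnorm(1 - rule$one_tailed_alpha) * sqrt(original$variance)
  else {
    if (is.na(original$df)) stop("t backend requires degrees of freedom")
    qt(1 - rule$one_tailed_alpha, original$df)
  }
}

#' Pair a significant original study with its replication
#'
#' Bundles the two studies with the significance rule that selected the
#' original.  Construction fails when the original is not statistically
#' significant under the rule (the hybrid model conditions on selection),
#' unless `force = TRUE`, which tags the pair as outside the model's
#' assumptions.
#'
#' @param original,replication [effect_estimate][g_from_t] objects on the
#'   same metric.
#' @param rule A [significance_rule()].
#' @param backend `"auto"` (t distribution for mean designs, normal for
#'   correlations), `"normal"`, or `"nct"`.
#' @param force Allow a non-significant original (results flagged).
#' @return An object of class `"study_pair"`.
#' @export
study_pair <- function(original, replication, rule = significance_rule(),
                       backend = c("auto", "normal", "nct"),
                       force = FALSE) {
  backend <- match.arg(backend)
  stopifnot(inherits(original, "effect_estimate"),
            inherits(replication, "effect_estimate"))
  if (original$metric != replication$metric)
    stop("original and replication must use the same effect size metric")
  if (backend == "auto")
    backend <- if (original$metric == "hedges_g") "nct" else "normal"
  if (backend == "nct" && (is.na(original$df) || is.na(replication$df)))
    stop("t backend requires mean-difference designs with degrees of freedom")

  mirrored <- rule$direction == "negative"
  if (mirrored) {
    original <- mirror_estimate(original)
    replication <- mirror_estimate(replication)
  }
  cv <- critical_value(original, rule, backend)
  significant <- if (backend == "nct") original$t_obs > cv else original$y > cv
  if (!significant && !force)
    stop("the original study is not statistically significant in the ",
         "expected direction under the selection rule (one-tailed alpha = ",
         rule$one_tailed_alpha, "); the hybrid model conditions on ",
         "significance.  Use force = TRUE to override.")
  structure(list(original = original, replication = replication,
                 rule = rule, backend = backend, critical_value = cv,
                 mirrored = mirrored, significant = significant),
            class = "study_pair")
}

mirror_estimate <- function(est) {
  est$y <- -est$y
  if (!is.na(est$t_obs)) est$t_obs <- -est$t_obs
  est
}

#' @export
print.study_pair <- function(x, digits = 4, ...) {
  cat("Study pair (", x$original$metric, ", backend ", x$backend, ")\n",
      sep = "")
  cat("  original:    y =", format(x$original$y, digits = digits),
      " se =", format(sqrt(x$original$variance), digits = digits), "\n")
  cat("  replication: y =", format(x$replication$y, digits = digits),
      " se =", format(sqrt(x$replication$variance), digits = digits), "\n")
  cat("  selection: one-tailed alpha =", x$rule$one_tailed_alpha,
      if (!x$significant) " [FORCED: original not significant]", "\n")
  invisible(x)
}

#' Conditional probability of the original study's evidence
#'
#' The probability of observing an effect at least as large as the
#' original's, given that it is statistically significant, at hypothesized
#' true effect `theta`:
#' \deqn{q_O = P(y \ge y_O; \theta) / P(y \ge y_O^{CV}; \theta).}
#' At the true effect, \eqn{q_O} is uniform on (0, 1) -- the p-uniform
#' principle.  Tail ratios are computed in log space so that extreme
#' `theta` cannot produce 0/0.
#'
#' @param pair A [study_pair()].
#' @param theta Hypothesized true effect(s) on the analysis scale.
#' @return Probabilities in `[1e-300, 1]`, same length as `theta`.
#' @export
q_original <- function(pair, theta) {
  o <- pair$original
  if (pair$backend == "nct") {
    ncp <- theta / o$correction_J * ncp_factor(o)
    lq <- log_nct_sf(o$t_obs, o$df, ncp) - log_nct_sf(pair$critical_value, o$df, ncp)
  } else {
    se <- sqrt(o$variance)
    lq <- pnorm(o$y, theta, se, lower.tail = FALSE, log.p = TRUE) -
      pnorm(pair$critical_value, theta, se, lower.tail = FALSE, log.p = TRUE)
  }
  pmin(pmax(exp(lq), 1e-300), 1)
}

#' Tail probability of the replication
#'
#' \eqn{q_R = P(y \ge y_R; \theta)}: the probability of an effect at least
#' as large as the replication's at hypothesized true effect `theta`.  The
#' replication is not selected on significance, so no conditioning applies.
#'
#' @inheritParams q_original
#' @return Probabilities in `[1e-300, 1]`, same length as `theta`.
#' @export
q_replication <- function(pair, theta) {
  r <- pair$replication
  if (pair$backend == "nct") {
    ncp <- theta / r$correction_J * ncp_factor(r)
    lq <- log_nct_sf(r$t_obs, r$df, ncp)
  } else {
    lq <- pnorm(r$y, theta, sqrt(r$variance), lower.tail = FALSE, log.p = TRUE)
  }
  pmin(pmax(exp(lq), 1e-300), 1)
}

#' Combined probability statistic of the hybrid method
#'
#' Sums the original's conditional probability and the replication's tail
#' probability, \eqn{x = q_O + q_R}.  Under the true effect each summand is
#' uniform, so x follows the two-term Irwin-Hall distribution; x is
#' non-decreasing in `theta`, which is what makes test inversion work.
#'
#' @inheritParams q_original
#' @return An object of class `"hybrid_diagnostics"`: a list with
#'   components `q_o`, `q_r`, `x` (each the length of `theta`) and `theta`.
#' @examples
#' p <- study_pair(g_from_t(2.211, 40, 40), g_from_t(1.040, 80, 80))
#' x_statistic(p, 0)  # q_O = 0.60, x = 0.75
#' @export
x_statistic <- function(pair, theta) {
  qo <- q_original(pair, theta)
  qr <- q_replication(pair, theta)
  structure(list(q_o = qo, q_r = qr, x = qo + qr, theta = theta),
            class = "hybrid_diagnostics")
}

#' @export
print.hybrid_diagnostics <- function(x, digits = 4, ...) {
  print(data.frame(theta = x$theta,
                   q_O = round(x$q_o, digits),
                   q_R = round(x$q_r, digits),
                   x = round(x$x, digits)), row.names = FALSE)
  invisible(x)
}
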