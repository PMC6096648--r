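#' Combine a significant original study with its replication
#'
#' Fits the full set of two-study meta-analytic methods to one statistically
#' significant original study and one replication: fixed-effect
#' meta-analysis, replication-only estimation, and the hybrid family
#' (hybrid, hybrid0, hybridR), which corrects the original study for its
#' selection on significance via the p-uniform principle.  Also attaches the
#' method-choice guideline and the observed-power diagnostic of the
#' original study.
#'
#' @param original,replication [effect_estimate][g_from_t] objects on a
#'   common metric, e.g. from [g_from_t()], [g_from_means()],
#'   [one_sample_g_from_t()] or [z_from_r()].
#' @param methods Which methods to fit; defaults to all five.
#' @param alpha Two-tailed significance level of the original study's
#'   selection test (default .05, i.e. one-tailed selection at .025).
#' @param direction Expected direction of the effect; `"negative"` mirrors
#'   the analysis and mirrors results back.
#' @param ci_level Confidence level for all intervals, default .95.
#' @param backend Sampling-distribution backend: `"auto"` uses the
#'   noncentral t for mean-difference designs and the normal for
#'   correlations.
#' @param expectation Prior belief about the population effect size,
#'   passed to [advise_method()].
#' @param force Allow a non-significant original study (see
#'   [study_pair()]); hybrid results are then outside the model's
#'   assumptions.
#' @return An object of class `"hybrid_meta"` with components `results`
#'   (a named list of `"method_result"` objects), `pair`, `advice`,
#'   `observed_power`, and `ci_level`.  Supports `print()`, `summary()`,
#'   `coef()`, `confint()`, `plot()` and `simulate()`.
#' @examples
#' fit <- hybrid_meta(g_from_t(2.211, 40, 40), g_from_t(1.040, 80, 80))
#' fit
#' coef(fit)
#' @export
hybrid_meta <- function(original, replication,
                        methods = c("fixed_effect", "replication",
                                    "hybrid", "hybrid0", "hybridR"),
                        alpha = 0.05,
                        direction = c("positive", "negative"),
                        ci_level = 0.95,
                        backend = c("auto", "normal", "nct"),
                        expectation = c("uncertain", "zero_or_small",
                                        "medium_or_large"),
                        force = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  rule <- significance_rule(alpha, match.arg(direction))
  pair <- study_pair(original, replication, rule, match.arg(backend), force)

  results <- lapply(methods, function(m) {
    res <- switch(m,
      fixed_effect = fixed_effect_meta(list(pair$original, pair$replication),
                                       ci_level),
      replication = replication_only(pair$replication, ci_level),
      hybrid = hybrid_fit(pair, ci_level),
      hybrid0 = hybrid0_fit(pair, ci_level),
      hybridR = hybridR_fit(pair, ci_level))
    if (pair$mirrored) mirror_result(res) else res
  })
  names(results) <- methods

  n_o <- total_n(original); n_r <- total_n(replication)
  structure(
    list(results = results, pair = pair, ci_level = ci_level,
         advice = advise_method(n_o, n_r, match.arg(expectation)),
         observed_power = original_observed_power(pair),
         n_original = n_o, n_replication = n_r),
    class = "hybrid_meta")
}

total_n <- function(est) {
  if (est$design == "two_sample_means") est$n1 + est$n2 else est$n
}

mirror_result <- function(res) {
  est <- res$estimate
  res$estimate <- -est
  ci <- c(-res$ci_high, -res$ci_low)
  res$ci_low <- ci[1]; res$ci_high <- ci[2]
  res
}

# observed power of the original study's test, evaluated at the
# replication's effect size estimate (guideline-consistent plug-in); the
# convention is a one-tailed test at the original's two-tailed alpha level
original_observed_power <- function(pair) {
  o <- pair$original; r <- pair$replication
  a1 <- pair$rule$alpha
  if (o$metric == "hedges_g") {
    d <- r$y / r$correction_J
    if (o$design == "two_sample_means")
      observed_power(d, o$n1, o$n2, a1)
    else
      pt(qt(1 - a1, o$df), o$df, d * sqrt(o$n), lower.tail = FALSE)
  } else {
    pnorm(abs(r$y) * sqrt(o$n - 3) - qnorm(1 - a1))
  }
}

#' @export
print.hybrid_meta <- function(x, digits = 3, ...) {
  cat("Meta-analysis of a significant original study and a replication\n")
  cat("  metric:", x$pair$original$metric,
      "  backend:", x$pair$backend,
      "  one-tailed selection alpha:", x$pair$rule$one_tailed_alpha, "\n\n")
  print(as.data.frame(x, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.hybrid_meta <- function(x, row.names = NULL, optional = FALSE,
                                      digits = NULL, ...) {
  rows <- lapply(x$results, function(r) {
    data.frame(method = method_label(r$method),
               estimate = r$estimate, ci_low = r$ci_low,
               ci_high = r$ci_high, p = r$p_two_tailed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (x$pair$original$metric == "fisher_z") {
    out$estimate_r <- tanh(out$estimate)
    out$ci_low_r <- tanh(out$ci_low)
    out$ci_high_r <- tanh(out$ci_high)
  }
  if (!is.null(digits))
    out[-1] <- lapply(out[-1], round, digits)
  rownames(out) <- row.names
  out
}

#' @export
summary.hybrid_meta <- function(object, digits = 3, ...) {
  structure(list(fit = object, digits = digits), class = "summary.hybrid_meta")
}

#' @export
print.summary.hybrid_meta <- function(x, ...) {
  fit <- x$fit
  print(fit, digits = x$digits)
  cat("\nObserved power of the original study (replication-based):",
      format(round(fit$observed_power, 2)), "\n")
  print(fit$advice)
  if (!fit$pair$significant)
    cat("WARNING: original study not significant under the selection rule;",
        "hybrid results are outside the model's assumptions.\n")
  invisible(x)
}

#' @export
coef.hybrid_meta <- function(object, ...) {
  vapply(object$results, `[[`, 0, "estimate")
}

#' @export
confint.hybrid_meta <- function(object, parm, level, ...) {
  if (!missing(level) && !isTRUE(all.equal(level, object$ci_level)))
    stop("intervals were computed at level ", object$ci_level,
         "; refit with ci_level = ", level)
  m <- t(vapply(object$results,
                function(r) c(r$ci_low, r$ci_high), numeric(2)))
  colnames(m) <- paste0(100 * c((1 - object$ci_level) / 2,
                                (1 + object$ci_level) / 2), " %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Plot the combined probability statistic against the hypothesized effect
#'
#' Draws \eqn{x(\theta) = q_O + q_R} over a range of hypothesized effects,
#' with the Irwin-Hall reference quantiles used for the hybrid estimate
#' (x = 1) and confidence bounds marked.  Visualizes the test inversion:
#' the estimate and CI are where the curve crosses the horizontal lines.
#'
#' @param x A `"hybrid_meta"` fit that includes the `"hybrid"` method.
#' @param n_points Number of curve evaluation points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hybrid_meta <- function(x, n_points = 200, ...) {
  hy <- x$results$hybrid
  if (is.null(hy)) stop("fit does not include the hybrid method")
  pad <- 0.25 * (hy$ci_high - hy$ci_low)
  th <- seq(hy$ci_low - pad, hy$ci_high + pad, length.out = n_points)
  if (x$pair$mirrored) th_eval <- -rev(th) else th_eval <- th
  xs <- x_statistic(x$pair, th_eval)$x
  if (x$pair$mirrored) xs <- rev(xs)
  graphics::plot(th, xs, type = "l", xlab = "hypothesized effect (theta)",
                 ylab = "x = q_O + q_R", ylim = c(0, 2), ...)
  lv <- qirwinhall(c((1 - x$ci_level) / 2, 0.5, (1 + x$ci_level) / 2))
  graphics::abline(h = lv, lty = c(3, 2, 3), col = "grey40")
  graphics::abline(v = c(hy$ci_low, hy$estimate, hy$ci_high),
                   lty = c(3, 2, 3), col = "steelblue")
  graphics::points(c(hy$ci_low, hy$estimate, hy$ci_high), lv,
                   pch = 19, col = "steelblue")
  invisible(x)
}

#' Simulate study pairs from a fitted model
#'
#' Draws new (significant original, replication) pairs at the fitted hybrid
#' effect size under the normal sampling model on the analysis scale, with
#' the original re-selected for significance by rejection sampling.
#'
#' @param object A `"hybrid_meta"` fit including the `"hybrid"` method.
#' @param nsim Number of pairs to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with columns `y_original` and `y_replication` on
#'   the analysis scale.
#' @export
simulate.hybrid_meta <- function(object, nsim = 1, seed = NULL, ...) {
  hy <- object$results$hybrid
  if (is.null(hy)) stop("fit does not include the hybrid method")
  if (!is.null(seed)) set.seed(seed)
  theta <- if (object$pair$mirrored) -hy$estimate else hy$estimate
  se_o <- sqrt(object$pair$original$variance)
  se_r <- sqrt(object$pair$replication$variance)
  ycv <- qnorm(1 - object$pair$rule$one_tailed_alpha) * se_o
  y_o <- draw_selected_normal(nsim, theta, se_o, ycv)
  y_r <- rnorm(nsim, theta, se_r)
  s <- if (object$pair$mirrored) -1 else 1
  data.frame(y_original = s * y_o, y_replication = s * y_r)
}

# rejection sampling of significant originals, in expanding batches
draw_selected_normal <- function(n, theta, se, ycv) {
  out <- numeric(0)
  accept <- max(pnorm(ycv, theta, se, lower.tail = FALSE), 1e-6)
  while (length(out) < n) {
    batch <- ceiling((n - length(out)) / accept * 1.2) + 100
    y <- rnorm(batch, theta, se)
    out <- c(out, y[y > ycv])
  }
  out[seq_len(n)]
}
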