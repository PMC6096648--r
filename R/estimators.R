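new_method_result <- function(method, estimate, ci_low, ci_high, statistic,
                              p_two_tailed, metric,
                              variance = NA_real_, p_one_tailed = NA_real_,
                              branch_taken = "n/a") {
  structure(list(method = method, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high,
                 statistic = statistic, p_two_tailed = p_two_tailed,
                 p_one_tailed = p_one_tailed, variance = variance,
                 branch_taken = branch_taken, metric = metric),
            class = "method_result")
}

#' @export
print.method_result <- function(x, digits = 3, ...) {
  cat(method_label(x$method), ": estimate ",
      format(round(x$estimate, digits), nsmall = digits),
      " (", format(round(x$ci_low, digits), nsmall = digits), "; ",
      format(round(x$ci_high, digits), nsmall = digits), ")",
      " [p = ", format(round(x$p_two_tailed, 4)), "]\n", sep = "")
  invisible(x)
}

method_label <- function(m) {
  c(fixed_effect = "Fixed-effect meta-analysis",
    replication = "Replication only",
    hybrid = "Hybrid", hybrid0 = "Hybrid0", hybridR = "HybridR")[[m]]
}

#' Fixed-effect meta-analysis of effect estimates
#'
#' Inverse-variance weighted pooling under the common-effect model
#' \eqn{y_i = \theta + \epsilon_i}, \eqn{\epsilon_i \sim N(0, \sigma_i^2)}:
#' \deqn{\hat\theta = \sum w_i y_i / \sum w_i, \quad w_i = 1/\hat\sigma_i^2,
#'   \quad v_{\hat\theta} = 1/\sum w_i,}
#' with a normal-theory confidence interval and two-tailed z test of no
#' effect.  No selection correction is applied.
#'
#' @param studies A list of [effect_estimate][g_from_t] objects on a common
#'   metric (a single object is promoted to a list of one).
#' @param ci_level Confidence level, default .95.
#' @return An object of class `"method_result"`.
#' @export
fixed_effect_meta <- function(studies, ci_level = 0.95) {
  if (inherits(studies, "effect_estimate")) studies <- list(studies)
  stopifnot(length(studies) >= 1,
            all(vapply(studies, inherits, TRUE, "effect_estimate")))
  metrics <- vapply(studies, `[[`, "", "metric")
  if (length(unique(metrics)) > 1)
    stop("all studies must use the same effect size metric")
  y <- vapply(studies, `[[`, 0, "y")
  w <- 1 / vapply(studies, `[[`, 0, "variance")
  est <- sum(w * y) / sum(w)
  v <- 1 / sum(w)
  z <- est / sqrt(v)
  zq <- qnorm((1 + ci_level) / 2)
  new_method_result("fixed_effect", est,
                    est - zq * sqrt(v), est + zq * sqrt(v),
                    statistic = z,
                    p_two_tailed = 2 * pnorm(abs(z), lower.tail = FALSE),
                    p_one_tailed = pnorm(z, lower.tail = FALSE),
                    variance = v, metric = metrics[1])
}

#' Estimation from the replication alone
#'
#' Maximum-likelihood estimation using only the replication: the estimate
#' is the observed effect, with a normal-theory interval and z test.  The
#' replication is assumed free of selection, so no correction is needed.
#'
#' @param replication An [effect_estimate][g_from_t].
#' @inheritParams fixed_effect_meta
#' @return An object of class `"method_result"`.
#' @export
replication_only <- function(replication, ci_level = 0.95) {
  stopifnot(inherits(replication, "effect_estimate"))
  se <- sqrt(replication$variance)
  z <- replication$y / se
  zq <- qnorm((1 + ci_level) / 2)
  new_method_result("replication", replication$y,
                    replication$y - zq * se, replication$y + zq * se,
                    statistic = z,
                    p_two_tailed = 2 * pnorm(abs(z), lower.tail = FALSE),
                    p_one_tailed = pnorm(z, lower.tail = FALSE),
                    variance = replication$variance,
                    metric = replication$metric)
}

# Solve x(theta) = target on the analysis scale.  x is non-decreasing in
# theta; the initial bracket is widened (doubled, up to 4 times) if it does
# not straddle the target.
solve_x <- function(pair, target, bracket = c(-6, 6)) {
  f <- function(th) x_statistic(pair, th)$x - target
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  tries <- 0
  while ((flo > 0 || fhi < 0) && tries < 4) {
    lo <- 2 * lo; hi <- 2 * hi
    flo <- f(lo); fhi <- f(hi)
    tries <- tries + 1
  }
  if (flo > 0 || fhi < 0)
    stop(sprintf(paste0("root of x(theta) = %.4f not bracketed in ",
                        "[%.1f, %.1f]: x ranges from %.4f to %.4f"),
                 target, lo, hi, flo + target, fhi + target))
  uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
          tol = 1e-10, maxiter = 200)$root
}

#' Hybrid estimate combining a significant original study and a replication
#'
#' Point estimation, test-inversion confidence interval and test of no
#' effect for the hybrid method.  The estimate is the `theta` at which the
#' combined statistic \eqn{x(\theta) = q_O + q_R} equals 1 (its null
#' median under the Irwin-Hall reference); because \eqn{x} is increasing in
#' `theta`, the CI bounds solve \eqn{x(\theta)} equal to the Irwin-Hall
#' `(1-ci_level)/2` and `(1+ci_level)/2` quantiles.  The two-tailed p value
#' is \eqn{G(x(0))}; the one-tailed p value is \eqn{F(x(0))}.
#'
#' @param pair A [study_pair()] whose original is significant.
#' @inheritParams fixed_effect_meta
#' @return An object of class `"method_result"`; `statistic` is
#'   \eqn{x(0)}.
#' @export
hybrid_fit <- function(pair, ci_level = 0.95) {
  stopifnot(inherits(pair, "study_pair"))
  est <- solve_x(pair, 1)
  lo <- solve_x(pair, qirwinhall((1 - ci_level) / 2))
  hi <- solve_x(pair, qirwinhall((1 + ci_level) / 2))
  x0 <- x_statistic(pair, 0)$x
  new_method_result("hybrid", est, lo, hi, statistic = x0,
                    p_two_tailed = irwinhall_two_tailed(x0),
                    p_one_tailed = pirwinhall(x0),
                    metric = pair$original$metric,
                    branch_taken = "hybrid")
}

#' Hybrid0: hybrid with the estimate truncated at zero
#'
#' Identical to [hybrid_fit()] except that the point estimate is set to 0
#' whenever the combined statistic at the null exceeds its median
#' (\eqn{x(0) > 1}), i.e. when the combined evidence points to a negative
#' effect.  The confidence interval and p values are inherited from the
#' hybrid fit; only the point estimate is truncated.
#'
#' @inheritParams hybrid_fit
#' @return An object of class `"method_result"`.
#' @export
hybrid0_fit <- function(pair, ci_level = 0.95) {
  res <- hybrid_fit(pair, ci_level)
  res$method <- "hybrid0"
  if (res$statistic > 1) {
    res$estimate <- 0
    res$branch_taken <- "zero"
  }
  res
}

#' HybridR: hybrid or replication, depending on the original's p value
#'
#' Returns the full hybrid result when the original study's two-tailed
#' p value is below half its significance level (below .025 for a .05-level
#' test) and the replication-only result otherwise.  A marginally
#' significant original (.025 < p < .05) implies a negative
#' selection-corrected effect, so its evidence is discarded.  Ties at the
#' threshold take the replication branch.
#'
#' @inheritParams hybrid_fit
#' @return An object of class `"method_result"` with `branch_taken` set to
#'   `"hybrid"` or `"replication"`.
#' @export
hybridR_fit <- function(pair, ci_level = 0.95) {
  p_o <- original_p_two_tailed(pair)
  if (p_o < pair$rule$alpha / 2) {
    res <- hybrid_fit(pair, ci_level)
    res$method <- "hybridR"
    res$branch_taken <- "hybrid"
  } else {
    res <- replication_only(pair$replication, ci_level)
    res$method <- "hybridR"
    res$branch_taken <- "replication"
  }
  res
}

original_p_two_tailed <- function(pair) {
  o <- pair$original
  if (pair$backend == "nct")
    2 * pt(abs(o$t_obs), o$df, lower.tail = FALSE)
  else
    2 * pnorm(abs(o$y) / sqrt(o$variance), lower.tail = FALSE)
}

#' Which method to use for a given original/replication setting
#'
#' Implements the decision guidelines derived from the methods' analytic
#' performance: with an uncertain population effect, use only the
#' replication when it is the larger study (1a) and hybridR otherwise (1b);
#' expecting a zero-to-small effect, use hybridR (2); expecting a medium or
#' larger effect, use fixed-effect meta-analysis (3).
#'
#' @param N_O,N_R Total sample sizes of the original study and replication.
#' @param expectation Prior belief about the population effect size.
#' @return An object of class `"guideline_advice"`: a list with
#'   `recommended`, `guideline_id` and `rationale`.
#' @export
advise_method <- function(N_O, N_R,
                          expectation = c("uncertain", "zero_or_small",
                                          "medium_or_large")) {
  check_count(N_O, 1, "N_O"); check_count(N_R, 1, "N_R")
  expectation <- match.arg(expectation)
  adv <- switch(expectation,
    uncertain = if (N_R > N_O)
      list("replication_only", "1a",
           "uncertain effect and the replication is the larger study: its estimate is unbiased and its test outperforms hybridR")
    else
      list("hybridR", "1b",
           "uncertain effect and the original is at least as large: the original contains enough information to improve RMSE and power"),
    zero_or_small = list("hybridR", "2",
           "expecting a zero or small effect: hybridR has low RMSE, small bias and better power; fixed-effect would overestimate"),
    medium_or_large = list("fixed_effect", "3",
           "expecting a medium or larger effect: fixed-effect bias is minor and it has the lowest RMSE and highest power"))
  structure(list(recommended = adv[[1]], guideline_id = adv[[2]],
                 rationale = adv[[3]]),
            class = "guideline_advice")
}

#' @export
print.guideline_advice <- function(x, ...) {
  cat("Guideline ", x$guideline_id, ": use ", x$recommended, "\n  (",
      x$rationale, ")\n", sep = "")
  invisible(x)
}

#' Power of the one-tailed two-sample t test
#'
#' Noncentral-t power of a one-tailed two-independent-groups t test at a
#' given standardized mean difference: \eqn{P(T_{df,ncp} > t_{crit})} with
#' \eqn{ncp = d\sqrt{n_1 n_2/(n_1+n_2)}}.  Used as an 'observed power'
#' diagnostic with the replication-based effect estimate plugged in for d.
#'
#' @param effect_d Standardized mean difference assumed true.
#' @param n1,n2 Per-group sample sizes.
#' @param alpha_one_tailed One-tailed significance level, default .05.
#' @return The power, a probability.
#' @examples
#' observed_power(0.164, 40, 40)  # 0.18
#' @export
observed_power <- function(effect_d, n1, n2, alpha_one_tailed = 0.05) {
  check_count(n1, 2, "n1"); check_count(n2, 2, "n2")
  stopifnot(alpha_one_tailed > 0, alpha_one_tailed < 1)
  df <- n1 + n2 - 2
  ncp <- effect_d * sqrt(n1 * n2 / (n1 + n2))
  pt(qt(1 - alpha_one_tailed, df), df, ncp, lower.tail = FALSE)
}
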