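#' Power of the one-tailed Fisher z test
#'
#' Probability that a study of size `N` with population correlation `rho`
#' produces a Fisher-z effect beyond the one-tailed critical value:
#' \deqn{\pi = \Phi(\mathrm{atanh}(\rho)\sqrt{N-3} - z_{1-\alpha}).}
#' Equals `alpha_one_tailed` when `rho = 0` (the selection rate under the
#' null).
#'
#' @param rho Population correlation in `[0, 1)`.
#' @param N Sample size (at least 4).
#' @param alpha_one_tailed One-tailed significance level, default .025.
#' @return The power, a probability.
#' @examples
#' selection_power(0.1, 783)  # 0.80
#' @export
selection_power <- function(rho, N, alpha_one_tailed = 0.025) {
  check_count(N, 4, "N")
  stopifnot(rho >= 0, rho < 1)
  pnorm(atanh(rho) * sqrt(N - 3) - qnorm(1 - alpha_one_tailed))
}

#' Deterministic percentile grid of the significant original study
#'
#' Discretizes the marginal distribution of a statistically significant
#' original effect (a normal on the Fisher-z scale truncated at the
#' selection threshold) by `grid_n` evenly spaced cumulative probabilities
#' \deqn{P_i^O = 1 - \pi + i\,\pi/(grid_n + 1), \quad i = 1, \dots, grid_n,}
#' where \eqn{\pi} is the selection power, and maps them to effect values
#' through the normal quantile function.  All effects exceed the selection
#' critical value.
#'
#' @inheritParams selection_power
#' @param grid_n Number of grid points, default 1000.
#' @return An object of class `"percentile_grid"`: a list with
#'   `probabilities`, `effects` (Fisher-z scale) and `pi`.
#' @export
significant_percentile_grid <- function(rho, N, alpha_one_tailed = 0.025,
                                        grid_n = 1000) {
  check_count(grid_n, 2, "grid_n")
  pi_sel <- selection_power(rho, N, alpha_one_tailed)
  i <- seq_len(grid_n)
  probs <- 1 - pi_sel + i * pi_sel / (grid_n + 1)
  structure(list(probabilities = probs,
                 effects = atanh(rho) + qnorm(probs) / sqrt(N - 3),
                 pi = pi_sel),
            class = "percentile_grid")
}

#' Deterministic percentile grid of the replication
#'
#' The replication is not selected, so its marginal distribution is
#' discretized by \eqn{P_i^R = i/(grid_n + 1)} mapped through the normal
#' quantile function on the Fisher-z scale.
#'
#' @inheritParams significant_percentile_grid
#' @return An object of class `"percentile_grid"` (with `pi = NA`).
#' @export
replication_percentile_grid <- function(rho, N, grid_n = 1000) {
  check_count(grid_n, 2, "grid_n")
  i <- seq_len(grid_n)
  probs <- i / (grid_n + 1)
  structure(list(probabilities = probs,
                 effects = atanh(rho) + qnorm(probs) / sqrt(N - 3),
                 pi = NA_real_),
            class = "percentile_grid")
}

eval_methods <- c("fixed_effect", "replication", "hybrid", "hybrid0",
                  "hybridR")

#' Analytic performance of all methods in one evaluation condition
#'
#' Evaluates the estimators and tests on the deterministic
#' `grid_n` x `grid_n` joint grid of (significant original, replication)
#' effects implied by a population correlation `rho` and sample sizes
#' `N_O`, `N_R` (numerical integration of the joint density; every cell has
#' equal weight).  All computation is on the Fisher-z scale with the normal
#' sampling model; estimates are back-transformed to correlations before
#' the summary metrics are taken.  Per-cell hybrid estimates are found by a
#' fixed-iteration vectorized bisection of \eqn{x(\theta) = 1} over all
#' cells simultaneously; hybrid coverage and rejection use the monotone
#' test-inversion identity (the CI contains `rho` exactly when
#' \eqn{x(\mathrm{atanh}\,\rho)} lies between the Irwin-Hall reference
#' quantiles), which is equivalent to root-finding the bounds.
#'
#' @inheritParams significant_percentile_grid
#' @param N_O,N_R Sample sizes of the original study and replication.
#' @param ci_level Confidence level for coverage, default .95.
#' @param methods Which methods to evaluate.
#' @param estimates If `FALSE`, skip the per-cell hybrid root-finding
#'   (much faster; the hybrid-family estimate columns are `NA`, while
#'   coverage and rejection rates are still exact).
#' @return A data frame of class `"condition_metrics"`, one row per
#'   method, with columns `mean_estimate`, `median_estimate`,
#'   `sd_estimate`, `rmse` (correlation scale), `coverage` and
#'   `rejection_rate`.
#' @export
evaluate_condition <- function(rho, N_O, N_R, alpha_one_tailed = 0.025,
                               grid_n = 1000, ci_level = 0.95,
                               methods = eval_methods, estimates = TRUE) {
  methods <- match.arg(methods, eval_methods, several.ok = TRUE)
  check_count(N_O, 4, "N_O"); check_count(N_R, 4, "N_R")
  theta0 <- atanh(rho)
  s_o <- 1 / sqrt(N_O - 3); s_r <- 1 / sqrt(N_R - 3)
  zq <- qnorm((1 + ci_level) / 2)
  z_alpha <- qnorm(1 - alpha_one_tailed)
  ycv <- z_alpha * s_o

  y_o <- rep(significant_percentile_grid(rho, N_O, alpha_one_tailed,
                                         grid_n)$effects, each = grid_n)
  y_r <- rep(replication_percentile_grid(rho, N_R, grid_n)$effects,
             times = grid_n)

  x_at <- function(theta) {
    lq <- pnorm(y_o, theta, s_o, lower.tail = FALSE, log.p = TRUE) -
      pnorm(ycv, theta, s_o, lower.tail = FALSE, log.p = TRUE)
    pmin(exp(lq), 1) + pnorm(y_r, theta, s_r, lower.tail = FALSE)
  }

  need_hybrid <- any(c("hybrid", "hybrid0", "hybridR") %in% methods)
  x0 <- xt <- hyb_est <- NULL
  if (need_hybrid) {
    x0 <- x_at(0)
    xt <- if (rho == 0) x0 else x_at(theta0)
    if (estimates) hyb_est <- bisect_x(x_at, length(y_o))
  }

  ih_lo <- qirwinhall((1 - ci_level) / 2)
  ih_hi <- qirwinhall((1 + ci_level) / 2)
  ih_alpha <- qirwinhall(alpha_one_tailed)

  per_method <- function(m) {
    if (m == "fixed_effect") {
      w_o <- 1 / s_o^2; w_r <- 1 / s_r^2
      est <- (w_o * y_o + w_r * y_r) / (w_o + w_r)
      se <- 1 / sqrt(w_o + w_r)
      reject <- est / se > z_alpha
      cover <- abs(est - theta0) <= zq * se
    } else if (m == "replication") {
      est <- y_r
      reject <- y_r / s_r > z_alpha
      cover <- abs(y_r - theta0) <= zq * s_r
    } else if (m == "hybrid" || m == "hybrid0") {
      est <- hyb_est
      if (m == "hybrid0" && !is.null(est)) est <- ifelse(x0 > 1, 0, est)
      reject <- x0 <= ih_alpha
      cover <- xt >= ih_lo & xt <= ih_hi
    } else { # hybridR
      p_o2 <- 2 * pnorm(y_o / s_o, lower.tail = FALSE)
      use_hyb <- p_o2 < alpha_one_tailed
      est <- if (is.null(hyb_est)) NULL else ifelse(use_hyb, hyb_est, y_r)
      reject <- ifelse(use_hyb, x0 <= ih_alpha, y_r / s_r > z_alpha)
      cover <- ifelse(use_hyb, xt >= ih_lo & xt <= ih_hi,
                      abs(y_r - theta0) <= zq * s_r)
    }
    if (is.null(est)) {
      stats_est <- rep(NA_real_, 4)
    } else {
      r_est <- tanh(est)
      bias <- mean(r_est) - rho
      sd_e <- sqrt(mean((r_est - mean(r_est))^2))
      stats_est <- c(mean(r_est), median(r_est), sd_e,
                     sqrt(bias^2 + sd_e^2))
    }
    data.frame(method = m, rho = rho, N_O = N_O, N_R = N_R,
               grid_n = grid_n,
               mean_estimate = stats_est[1], median_estimate = stats_est[2],
               sd_estimate = stats_est[3], rmse = stats_est[4],
               coverage = mean(cover), rejection_rate = mean(reject),
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(methods, per_method))
  class(out) <- c("condition_metrics", "data.frame")
  out
}

# vectorized bisection of x(theta) = 1 over all grid cells; x is
# non-decreasing in theta and the bracket [-10, 10] (Fisher-z scale)
# always straddles the root up to tanh saturation (|tanh(10) - 1| < 5e-9,
# far below grid resolution on the correlation scale)
bisect_x <- function(x_at, n, lower = -10, upper = 10, iterations = 60) {
  lo <- rep(lower, n); hi <- rep(upper, n)
  for (k in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    high <- x_at(mid) >= 1
    hi[high] <- mid[high]
    lo[!high] <- mid[!high]
  }
  (lo + hi) / 2
}

#' Evaluate many conditions at once
#'
#' Applies [evaluate_condition()] to each row of a condition table and
#' binds the tidy per-method results.
#'
#' @param conditions A data frame with columns `rho`, `N_O`, `N_R`.
#' @param ... Passed on to [evaluate_condition()].
#' @return A data frame of class `"condition_metrics"`.
#' @export
evaluate_grid <- function(conditions, ...) {
  stopifnot(all(c("rho", "N_O", "N_R") %in% names(conditions)))
  if (nrow(conditions) == 0) {
    out <- data.frame(method = character(0), rho = numeric(0),
                      N_O = numeric(0), N_R = numeric(0),
                      grid_n = numeric(0), mean_estimate = numeric(0),
                      median_estimate = numeric(0), sd_estimate = numeric(0),
                      rmse = numeric(0), coverage = numeric(0),
                      rejection_rate = numeric(0))
    class(out) <- c("condition_metrics", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
    evaluate_condition(conditions$rho[i], conditions$N_O[i],
                       conditions$N_R[i], ...)
  }))
  class(out) <- c("condition_metrics", "data.frame")
  out
}

#' Simulate a (significant original, replication) study pair
#'
#' Monte-Carlo counterpart of the analytic grid: draws the original's
#' Fisher-z effect from its selected (truncated) normal distribution by
#' rejection sampling and the replication's effect unconditionally, both at
#' population correlation `rho`.
#'
#' @inheritParams evaluate_condition
#' @param rule A [significance_rule()]; its one-tailed level is the
#'   selection threshold.
#' @param seed Integer seed; identical seeds give identical pairs.
#' @return A [study_pair()] on the Fisher-z scale (normal backend).
#' @export
simulate_pair <- function(rho, N_O, N_R, rule = significance_rule(),
                          seed = NULL) {
  d <- simulate_pairs(1, rho, N_O, N_R, rule, seed)
  o <- new_effect_estimate("fisher_z", d$y_original, 1 / (N_O - 3),
                           "correlation", n = as.integer(N_O))
  r <- new_effect_estimate("fisher_z", d$y_replication, 1 / (N_R - 3),
                           "correlation", n = as.integer(N_R))
  study_pair(o, r, rule, backend = "normal")
}

#' Simulate many study pairs
#'
#' Vectorized version of [simulate_pair()] returning a data frame of
#' Fisher-z effects; used for property checks (e.g. uniformity of the
#' conditional probabilities at the true effect).
#'
#' @inheritParams simulate_pair
#' @param reps Number of pairs.
#' @return A data frame with columns `y_original` and `y_replication`.
#' @export
simulate_pairs <- function(reps, rho, N_O, N_R,
                           rule = significance_rule(), seed = NULL) {
  check_count(N_O, 4, "N_O"); check_count(N_R, 4, "N_R")
  if (!is.null(seed)) set.seed(seed)
  theta0 <- atanh(rho)
  s_o <- 1 / sqrt(N_O - 3); s_r <- 1 / sqrt(N_R - 3)
  ycv <- qnorm(1 - rule$one_tailed_alpha) * s_o
  data.frame(y_original = draw_selected_normal(reps, theta0, s_o, ycv),
             y_replication = rnorm(reps, theta0, s_r))
}
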