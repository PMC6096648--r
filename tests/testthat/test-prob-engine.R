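test_that("critical value matches the selection rule on both backends", {
  est <- z_from_r(0.45, 23)  # se = 1/sqrt(20)
  se <- sqrt(est$variance)
  expect_equal(critical_value(est, significance_rule(0.05), "normal"),
               qnorm(0.975) * se, tolerance = 1e-12)
  expect_equal(round(critical_value(example_original(), backend = "normal") /
                       sqrt(example_original()$variance) * 0.2271, 3), 0.445)
  expect_equal(critical_value(example_original(), backend = "nct"),
               qt(0.975, 78), tolerance = 1e-12)
  # rule whose one-tailed level is the upper tail beyond 1 se
  rule1 <- significance_rule(2 * pnorm(-1))
  est1 <- z_from_r(0.9, 4)   # variance exactly 1
  expect_equal(critical_value(est1, rule1, "normal"), 1, tolerance = 1e-12)
  expect_error(significance_rule(1.2), "alpha")
})

test_that("pair construction enforces the significance assumption", {
  expect_s3_class(example_pair(), "study_pair")
  weak <- z_from_r(0.1, 31)
  expect_error(study_pair(weak, z_from_r(0.2, 31)), "not statistically significant")
  forced <- study_pair(weak, z_from_r(0.2, 31), force = TRUE)
  expect_false(forced$significant)
  expect_error(study_pair(example_original(), z_from_r(0.2, 31)),
               "same effect size metric")
})

test_that("conditional probability of the original reproduces the example", {
  p <- example_pair()
  expect_equal(q_original(p, 0), 0.015 / 0.025, tolerance = 0.005 / 0.6)
  # observed effect exactly at the critical value: q_O = 1 at every theta
  at_cv <- study_pair(z_from_r(tanh(qnorm(0.975) / sqrt(28)), 31),
                      z_from_r(0.1, 31), force = TRUE, backend = "normal")
  expect_equal(q_original(at_cv, c(-2, -0.5, 0, 0.7, 3)), rep(1, 5),
               tolerance = 1e-9)
  # hypothesized effects far below the data: q_O vanishes but stays finite
  cp <- correlation_pair()
  qs <- q_original(cp, c(-40, -10, -5))
  expect_true(all(qs >= 1e-300 & qs < 1e-3))
})

test_that("replication probability is its upper-tail p value", {
  p <- example_pair()
  expect_equal(q_replication(p, 0), 0.3 / 2, tolerance = 0.005 / 0.15)
  cp <- correlation_pair()
  expect_equal(q_replication(cp, cp$replication$y), 0.5, tolerance = 1e-12)
  far <- study_pair(z_from_r(0.45, 31), z_from_r(0.9999, 8),
                    backend = "normal")
  expect_lt(q_replication(far, 0), 1e-10)
})

test_that("x statistic sums the probabilities and is monotone in theta", {
  p <- example_pair()
  d0 <- x_statistic(p, 0)
  expect_equal(d0$x, d0$q_o + d0$q_r, tolerance = 1e-15)
  expect_equal(d0$x, 0.75, tolerance = 0.005 / 0.75)
  expect_equal(x_statistic(p, 6)$x, 2, tolerance = 1e-6)
  for (pair in list(p, correlation_pair())) {
    xs <- x_statistic(pair, seq(-3, 3, by = 0.05))$x
    expect_true(all(diff(xs) >= -1e-10))
    expect_true(all(xs >= 0 & xs <= 2))
  }
})

test_that("noncentral-t log tail matches stats::pt where pt is reliable", {
  # pt()'s noncentral algorithm is accurate to ~1e-12 in absolute terms,
  # so compare on the probability scale at that accuracy, and demand full
  # relative agreement only where the tail is not small
  for (df in c(5, 78, 158)) {
    for (ncp in c(-2, 0, 1.5, 4)) {
      for (t in c(-1, 0.5, 2.211, 4)) {
        p_ours <- exp(log_nct_sf(t, df, ncp))
        p_ref <- pt(t, df, ncp, lower.tail = FALSE)
        expect_lt(abs(p_ours - p_ref), 1e-11)
        if (p_ref > 1e-3)
          expect_equal(p_ours, p_ref, tolerance = 1e-8)
      }
    }
  }
})

test_that("noncentral-t log tail stays smooth where pt underflows", {
  # far left tail: the ratio must decrease smoothly in theta, while the
  # pt-based ratio is dominated by its ~1e-12 absolute error there
  lr <- function(ncp) log_nct_sf(2.211, 78, ncp) - log_nct_sf(qt(0.975, 78), 78, ncp)
  ncps <- seq(-10, -2, by = 0.25)
  vals <- vapply(ncps, lr, 0)
  expect_true(all(is.finite(vals)))
  expect_true(all(diff(vals) > 0))  # q_O increasing in ncp (hence in theta)
})

test_that("q_O and q_R are uniform at the true effect size", {
  rule <- significance_rule()
  rho <- 0.3; n_o <- 55; n_r <- 31
  theta0 <- atanh(rho)
  sims <- simulate_pairs(1e4, rho, n_o, n_r, rule, seed = 2024)
  q <- vapply(seq_len(nrow(sims)), function(i) {
    o <- z_from_r(tanh(sims$y_original[i]), n_o)
    r <- z_from_r(tanh(sims$y_replication[i]), n_r)
    pr <- study_pair(o, r, rule, backend = "normal")
    c(q_original(pr, theta0), q_replication(pr, theta0))
  }, numeric(2))
  expect_gt(suppressWarnings(ks.test(q[1, ], "punif"))$p.value, 1e-4)
  expect_gt(suppressWarnings(ks.test(q[2, ], "punif"))$p.value, 1e-4)
})

test_that("negative expected direction mirrors the analysis", {
  rule <- significance_rule(direction = "negative")
  p <- study_pair(g_from_t(-2.211, 40, 40), g_from_t(-1.040, 80, 80), rule)
  expect_equal(p$original$t_obs, 2.211)
  expect_true(p$significant)
})
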