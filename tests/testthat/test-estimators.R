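test_that("fixed-effect meta-analysis reproduces the published pooling", {
  fe <- fixed_effect_meta(list(example_original(), example_replication()))
  expect_equal(round(fe$estimate, 3), 0.270)
  expect_equal(round(c(fe$ci_low, fe$ci_high), 3), c(0.016, 0.525))
  expect_equal(fe$p_two_tailed, 0.0375, tolerance = 0.002)
  expect_equal(round(fe$statistic, 3), 2.081)
})

test_that("fixed-effect weighting limits", {
  a <- z_from_r(0.2, 43); b <- z_from_r(0.5, 43)  # equal variances
  expect_equal(fixed_effect_meta(list(a, b))$estimate, (a$y + b$y) / 2,
               tolerance = 1e-12)
  single <- fixed_effect_meta(list(a))
  expect_equal(single$estimate, a$y, tolerance = 1e-12)
  expect_equal(single$variance, a$variance, tolerance = 1e-12)
  k <- 5
  same <- fixed_effect_meta(rep(list(a), k))
  expect_equal(same$variance, a$variance / k, tolerance = 1e-12)
  expect_error(fixed_effect_meta(list(a, example_original())), "same effect size metric")
})

test_that("replication-only estimation is normal-theory ML", {
  r <- replication_only(example_replication())
  expect_equal(round(r$estimate, 3), 0.164)
  expect_equal(round(c(r$ci_low, r$ci_high), 3), c(-0.147, 0.474))
  expect_equal(r$p_two_tailed, 0.302, tolerance = 0.01)
  expect_equal(r$ci_high - r$ci_low,
               2 * qnorm(0.975) * sqrt(r$variance), tolerance = 1e-12)
  null <- replication_only(z_from_r(0, 40))
  expect_identical(null$p_two_tailed, 1)
})

test_that("hybrid fit solves the test inversion for the example pair", {
  h <- hybrid_fit(example_pair())
  expect_equal(h$estimate, 0.103, tolerance = 0.005 / 0.103)
  expect_equal(h$p_two_tailed, 0.561, tolerance = 0.005 / 0.561)
  expect_equal(h$ci_high, 0.428, tolerance = 0.02 / 0.428)
  # lower bound frozen from a high-precision quadrature oracle
  # (cross-checked against an independent Boost-based implementation)
  expect_equal(h$ci_low, -1.2223, tolerance = 1e-3)
  expect_lt(abs(x_statistic(example_pair(), h$estimate)$x - 1), 1e-8)
  expect_lt(h$ci_low, h$estimate)
  expect_gt(h$ci_high, h$estimate)
})

test_that("hybrid estimate agrees with a dense-grid oracle", {
  cp <- correlation_pair()
  h <- hybrid_fit(cp)
  grid <- seq(-0.5, 1, by = 1e-4)
  oracle <- grid[which.min(abs(x_statistic(cp, grid)$x - 1))]
  expect_lt(abs(h$estimate - oracle), 1e-3)
})

test_that("hybrid test and confidence interval cohere", {
  set.seed(7)
  for (i in 1:25) {
    sims <- simulate_pairs(1, 0.2, 31, 55)
    pr <- study_pair(
      z_from_r(tanh(sims$y_original), 31),
      z_from_r(tanh(sims$y_replication), 55), backend = "normal")
    h <- hybrid_fit(pr)
    outside <- h$ci_low > 0 || h$ci_high < 0
    expect_identical(outside, h$p_two_tailed < 0.05)
  }
})

test_that("hybrid0 truncates only the point estimate", {
  h0 <- hybrid0_fit(example_pair())
  h <- hybrid_fit(example_pair())
  expect_equal(h0$estimate, h$estimate, tolerance = 1e-12)  # x(0) < 1 here
  expect_identical(h0$ci_low, h$ci_low)
  expect_identical(h0$p_two_tailed, h$p_two_tailed)
  # a pair whose combined evidence at the null points negative: x(0) > 1
  neg <- study_pair(z_from_r(0.38, 31), z_from_r(-0.25, 55),
                    backend = "normal")
  expect_gt(x_statistic(neg, 0)$x, 1)
  h0n <- hybrid0_fit(neg)
  expect_identical(h0n$estimate, 0)
  expect_identical(h0n$branch_taken, "zero")
  hn <- hybrid_fit(neg)
  expect_identical(h0n$ci_low, hn$ci_low)    # CI inherited untruncated
  expect_lt(hn$estimate, 0)
})

test_that("hybridR switches on the original's two-tailed p value", {
  # example: p_O = .03 > .025, so the replication branch is taken
  hr <- hybridR_fit(example_pair())
  rep_fit <- replication_only(example_replication())
  expect_identical(hr$branch_taken, "replication")
  expect_identical(hr$estimate, rep_fit$estimate)
  expect_identical(c(hr$ci_low, hr$ci_high), c(rep_fit$ci_low, rep_fit$ci_high))
  expect_identical(hr$p_two_tailed, rep_fit$p_two_tailed)
  # strongly significant original: identical to the full hybrid fit
  strong <- study_pair(z_from_r(0.55, 31), z_from_r(0.2, 55),
                       backend = "normal")
  expect_lt(original_p <- 2 * pnorm(strong$original$y /
              sqrt(strong$original$variance), lower.tail = FALSE), 0.025)
  hrs <- hybridR_fit(strong)
  hs <- hybrid_fit(strong)
  expect_identical(hrs$estimate, hs$estimate)
  expect_identical(hrs$ci_low, hs$ci_low)
  expect_identical(hrs$p_two_tailed, hs$p_two_tailed)
  expect_identical(hrs$branch_taken, "hybrid")
})

test_that("method advisor reproduces the guideline table", {
  cases <- list(
    list(80, 160, "uncertain", "replication_only", "1a"),
    list(96, 31, "uncertain", "hybridR", "1b"),
    list(50, 50, "uncertain", "hybridR", "1b"),      # N_R <= N_O
    list(31, 96, "zero_or_small", "hybridR", "2"),
    list(96, 31, "zero_or_small", "hybridR", "2"),
    list(40, 40, "medium_or_large", "fixed_effect", "3"),
    list(31, 783, "medium_or_large", "fixed_effect", "3"))
  for (cs in cases) {
    adv <- advise_method(cs[[1]], cs[[2]], cs[[3]])
    expect_identical(adv$recommended, cs[[4]])
    expect_identical(adv$guideline_id, cs[[5]])
  }
})

test_that("observed power of the one-tailed t test", {
  expect_equal(observed_power(0.164, 40, 40, 0.05), 0.18, tolerance = 0.01 / 0.18)
  expect_equal(observed_power(0, 40, 40, 0.05), 0.05, tolerance = 1e-10)
  expect_gt(observed_power(3, 40, 40, 0.05), 0.999)
})
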