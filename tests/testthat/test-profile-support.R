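test_that("profile likelihood has the exact null gap and the exposure-only tail", {
  pair <- fig_pair()
  ce <- corrected_estimate(pair, gw_rule())
  pl <- profile_loglik(c(0, ce$b_hat), pair, gw_rule())
  # pl(b_hat) - pl(0) = T / 2 exactly
  expect_equal(pl[2] - pl[1], ce$statistic / 2, tolerance = 1e-8)
  # pl(b) <= pl(b_hat) everywhere
  grid <- c(seq(-5, 60, by = 2.5), ce$b_hat)
  expect_true(all(profile_loglik(grid, pair, gw_rule()) <= pl[2] + 1e-10))
  # tail limit: log Lx(0) + log Ly(y) as |b| -> Inf
  tail_val <- cond_log_density(pair$x, 0, 1, gw_rule()) +
    dnorm(pair$y, pair$y, 1, log = TRUE)
  expect_equal(profile_loglik(1e6, pair, gw_rule()), tail_val, tolerance = 1e-3)
  expect_equal(profile_loglik(-1e6, pair, gw_rule()), tail_val, tolerance = 1e-3)
})

test_that("support units calibrate to chi-square tail levels", {
  expect_equal(k_from_alpha(0.05, 1), 1.92, tolerance = 1e-2)
  expect_equal(k_from_alpha(0.05, 1), qnorm(0.975)^2 / 2, tolerance = 1e-12)
  expect_equal(round(k_from_alpha(0.05, 84), 1), 5.9)
  expect_equal(k_from_alpha(0.3173, 1), 0.5, tolerance = 1e-3)
  expect_error(k_from_alpha(1.2), "alpha")
})

test_that("worked-example support has a finite lower limit and an unbounded upper limit", {
  s <- suppressWarnings(support_interval(fig_pair(), gw_rule(), k = 2))
  expect_equal(s$b_hat, 33.41195, tolerance = 1e-5)
  expect_equal(s$lower, 2.1411, tolerance = 1e-3)
  expect_true(s$lower_bounded)
  # unbounded above: certified by the tail test, hence in particular the
  # profile stays above the cut at b = 43.406
  expect_false(s$upper_bounded)
  expect_gt(profile_loglik(43.406, fig_pair(), gw_rule()), s$pl_max - 2)
  expect_gt(s$tail_value, s$pl_max - 2)
  expect_false(s$contains_zero)
  # the profile at the bounded limit sits exactly at the cut
  expect_equal(profile_loglik(s$lower, fig_pair(), gw_rule()),
               s$pl_max - 2, tolerance = 1e-6)
  # a disconnected likelihood set is flagged
  expect_warning(support_interval(fig_pair(), gw_rule(), k = 2),
                 "disconnected")
})

test_that("support degenerates to the point estimate as k shrinks and nests as k grows", {
  pair <- summary_pair(8, 1, 4, 1)
  s_tiny <- support_interval(pair, gw_rule(), k = 1e-8)
  expect_equal(s_tiny$lower, s_tiny$b_hat, tolerance = 1e-3)
  expect_equal(s_tiny$upper, s_tiny$b_hat, tolerance = 1e-3)
  s1 <- support_interval(pair, gw_rule(), k = 1)
  s2 <- support_interval(pair, gw_rule(), k = 2)
  expect_lt(s2$lower, s1$lower)
  expect_gt(s2$upper, s1$upper)
  expect_true(s1$lower <= s1$b_hat && s1$b_hat <= s1$upper)
  # bounded limits sit on the cut
  expect_equal(profile_loglik(c(s2$lower, s2$upper), pair, gw_rule()),
               rep(s2$pl_max - 2, 2), tolerance = 1e-6)
})

test_that("the k-unit support excludes zero exactly when T exceeds 2k", {
  set.seed(13)
  rule <- gw_rule()
  for (pair in random_selected_pairs(20, b = 0.3)) {
    t_stat <- conditional_test(pair)$statistic
    for (k in c(0.5, 2, 5.9)) {
      s <- suppressWarnings(support_interval(pair, rule, k = k))
      expect_identical(s$contains_zero, t_stat < 2 * k)
      # cross-check the flag against the profile itself
      expect_identical(
        profile_loglik(0, pair, rule) > s$pl_max - k, s$contains_zero)
      # membership of zero in the located interval agrees when both
      # limits exist on the component containing b_hat
      if (s$lower_bounded && s$upper_bounded) {
        expect_identical(s$lower < 0 && 0 < s$upper, s$contains_zero)
      }
    }
  }
})
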