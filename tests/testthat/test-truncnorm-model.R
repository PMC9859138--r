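test_that("alpha bounds follow their definition and collapse without selection", {
  expect_equal(alpha_bounds(0, 1, selection_rule(2)),
               c(alpha1 = -2, alpha2 = 2))
  expect_equal(alpha_bounds(4, 1, gw_rule()),
               c(alpha1 = -9.45131, alpha2 = 1.45131))
  expect_equal(alpha_bounds(4, 2, selection_rule(0)),
               c(alpha1 = -2, alpha2 = -2))
  expect_error(alpha_bounds(0, -1, gw_rule()), "positive")
  # gap is always 2 tau
  ab <- alpha_bounds(rnorm(20), 1.7, selection_rule(3))
  expect_equal(unname(ab[, "alpha2"] - ab[, "alpha1"]), rep(6, 20))
})

test_that("selection probability matches the normal-tail oracle and stays precise in log space", {
  expect_equal(selection_prob(0, 1, selection_rule(0)), 1)
  # at mu = 0 the selection probability is the two-sided p at the threshold
  expect_equal(selection_prob(0, 1, gw_rule()), 2 * pnorm(-5.45131),
               tolerance = 1e-12)
  expect_equal(selection_prob(0, 1, gw_rule()), 5e-8, tolerance = 1e-5)
  # independent tail arithmetic
  expect_equal(selection_prob(4, 1, gw_rule()),
               1 - pnorm(1.45131) + pnorm(-9.45131), tolerance = 1e-12)
  expect_equal(selection_prob(4, 1, gw_rule()), 0.0733, tolerance = 1e-3)
  # log form keeps relative precision where 1 - pnorm() would not
  expect_equal(selection_prob(0, 1, selection_rule(10), log = TRUE),
               log(2) + pnorm(10, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-12)
  # Monte-Carlo rejection frequency cross-check
  set.seed(42)
  z <- rnorm(1e6, 4, 1)
  p_hat <- mean(abs(z) >= 5.45131)
  se <- sqrt(p_hat * (1 - p_hat) / 1e6)
  expect_lt(abs(p_hat - selection_prob(4, 1, gw_rule())), 3 * se)
})

test_that("conditional log-density reduces, evaluates, and normalizes", {
  # tau = 0: plain normal log-density
  for (args in list(c(1.3, 0.5, 2), c(-4, 1, 0.3))) {
    expect_equal(cond_log_density(args[1], args[2], args[3], selection_rule(0)),
                 dnorm(args[1], args[2], args[3], log = TRUE))
  }
  # direct arithmetic from density and selection probability
  expect_equal(cond_log_density(6, 0, 1, gw_rule()),
               dnorm(6, log = TRUE) - log(2 * pnorm(-5.45131)),
               tolerance = 1e-12)
  expect_error(cond_log_density(3, 0, 1, gw_rule()), "truncation band")
  # quadrature: integrates to 1 over the two tails
  tau <- 5.45131
  f <- function(t) exp(cond_log_density(t, 2, 1, gw_rule()))
  total <- integrate(f, tau, Inf, rel.tol = 1e-12)$value +
    integrate(f, -Inf, -tau, rel.tol = 1e-12)$value
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("conditional mean and variance match closed-form limits and scale", {
  expect_equal(cond_mean(1.3, 2, selection_rule(0)), 1.3)
  expect_equal(cond_var(1.3, 2, selection_rule(0)), 4)
  # symmetry: zero mean stays zero under any truncation
  expect_equal(cond_mean(0, 1, selection_rule(3)), 0)
  expect_equal(cond_mean(0, 1, gw_rule()), 0)
  # scale equivariance of the variance at mu = 0
  expect_equal(cond_var(0, 2, selection_rule(3)),
               4 * cond_var(0, 1, selection_rule(3)), tolerance = 1e-12)
})

test_that("conditional moments agree with the inverse-CDF sampling oracle", {
  set.seed(7)
  n <- 1e6
  for (mu in c(0, 1, 4)) {
    for (tau in c(2, 5.45131)) {
      z <- rtrunc2_invcdf(n, mu, 1, tau)
      rule <- selection_rule(tau)
      expect_lt(abs(mean(z) - cond_mean(mu, 1, rule)),
                3 * sd(z) / sqrt(n))
      expect_lt(abs(var(z) - cond_var(mu, 1, rule)), 3 * se_of_var(z))
    }
  }
})

test_that("conditional moments agree with the rejection-sampling oracle where feasible", {
  set.seed(8)
  z <- rtrunc2_reject(1e6, 4, 1, 5.45131)
  expect_lt(abs(mean(z) - cond_mean(4, 1, gw_rule())), 3 * sd(z) / sqrt(1e6))
  expect_lt(abs(var(z) - cond_var(4, 1, gw_rule())), 3 * se_of_var(z))
})

test_that("score residual has the sign of x and vanishes at the MLE", {
  rule <- gw_rule()
  for (x in c(5.46, 6, 7.5, -5.8, -9)) {
    pair <- summary_pair(x, 1, 0, 1)
    expect_equal(sign(score_residual(0, pair, rule)), sign(x))
    fit <- fit_mu_x(pair, rule)
    expect_lt(abs(score_residual(fit$mu_x_hat, pair, rule)), 1e-8)
  }
  # tau = 0: the root is x itself
  pair <- summary_pair(2.2, 1, 0, 1)
  expect_equal(fit_mu_x(pair, selection_rule(0))$mu_x_hat, 2.2)
})

test_that("the truncated MLE shrinks, is odd, monotone, and a local maximum", {
  rule <- gw_rule()
  # worked example: strong shrinkage just above the threshold
  fit <- fit_mu_x(fig_pair(), rule)
  expect_true(fit$converged)
  expect_equal(fit$mu_x_hat, 0.3685957, tolerance = 1e-6)
  # fixed point: observed x equals the conditional mean at the MLE
  expect_equal(cond_mean(fit$mu_x_hat, 1, rule), 5.4599, tolerance = 1e-8)
  # shrinkage on a grid, both signs; the correction decays like the normal
  # tail phi(tau - z), so strictness is only testable while it exceeds the
  # solver tolerance
  zs <- seq(5.45131, 15.45131, length.out = 41)
  mus <- vapply(zs, function(z)
    fit_mu_x(summary_pair(z, 1, 0, 1), rule)$mu_x_hat, numeric(1))
  expect_true(all(mus > 0 & mus <= zs))
  expect_true(all(mus[zs <= 10] < zs[zs <= 10]))
  # monotone increasing in x
  expect_true(all(diff(mus) > 0))
  # odd symmetry
  mus_neg <- vapply(zs, function(z)
    fit_mu_x(summary_pair(-z, 1, 0, 1), rule)$mu_x_hat, numeric(1))
  expect_equal(mus_neg, -mus, tolerance = 1e-9)
  # local maximum of the conditional log-likelihood
  eps <- 1e-4
  for (z in c(5.46, 7.5, 12)) {
    f <- fit_mu_x(summary_pair(z, 1, 0, 1), rule)
    expect_gte(f$loglik, cond_log_density(z, f$mu_x_hat + eps, 1, rule))
    expect_gte(f$loglik, cond_log_density(z, f$mu_x_hat - eps, 1, rule))
  }
  # unselected SNP is refused
  expect_error(fit_mu_x(summary_pair(4, 1, 0, 1), rule), "selection")
})

test_that("shrinkage fades for strong instruments", {
  # at z = 7.5 the gap is just above 0.05; by z = 8 it is far smaller
  gap <- function(z) z - fit_mu_x(summary_pair(z, 1, 0, 1), gw_rule())$mu_x_hat
  expect_equal(gap(7.5), 0.0560936, tolerance = 1e-5)
  expect_lt(gap(7.55), 0.05)
  expect_lt(gap(8), 0.02)
})
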