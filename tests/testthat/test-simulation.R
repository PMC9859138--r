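small_cfg <- function(...) sim_config(n_draws = 20000L, seed = 1L, ...)

test_that("selected pairs follow the generative model of the study", {
  cfg <- small_cfg()
  pairs <- generate_selected_pairs(cfg, b = 1)
  # all retained draws pass selection
  expect_true(all(abs(pairs$x) >= cfg$tau))
  # retention fraction within 3 binomial standard errors of the tail oracle
  p <- 1 - pnorm(cfg$tau - cfg$mu_x) + pnorm(-cfg$tau - cfg$mu_x)
  n_sel <- nrow(pairs)
  expect_lt(abs(n_sel / cfg$n_draws - p),
            3 * sqrt(p * (1 - p) / cfg$n_draws))
  # no selection keeps every draw
  cfg0 <- small_cfg(tau = 0)
  expect_equal(nrow(generate_selected_pairs(cfg0, 0)), cfg0$n_draws)
  # determinism under a fixed seed
  expect_identical(pairs, generate_selected_pairs(cfg, b = 1))
  # hopeless threshold errors out
  expect_error(generate_selected_pairs(
    sim_config(n_draws = 100L, mu_x = 0, tau = 8, seed = 1), 0), "selection")
})

test_that("per-b substreams make runs reproducible and extensible", {
  t1 <- run_table1(small_cfg(b_values = c(0, 2)))
  t2 <- run_table1(small_cfg(b_values = c(0, 2)))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # adding a b value does not perturb existing rows
  t3 <- run_table1(small_cfg(b_values = c(0, 1, 2)))
  expect_identical(as.data.frame(t3[t3$b %in% c(0, 2), ]),
                   as.data.frame(t1), ignore_attr = TRUE)
})

test_that("null sampling distribution of the corrected estimator is symmetric about zero", {
  # full study scale: the fits are cheap and the symmetry checks need the
  # resolution of the ~7,300 selected draws
  b_hat <- simulate_b_hat(sim_config(seed = 1L), b = 0)
  n <- length(b_hat)
  # sign balance within 3 binomial standard errors
  expect_lt(abs(mean(b_hat > 0) - 0.5), 3 * sqrt(0.25 / n))
  # two-sided Kolmogorov-Smirnov: one independent half against the mirror
  # of the other (mirroring the same sample would make the halves dependent
  # and the KS null invalid)
  h <- seq_len(n %/% 2)
  expect_gt(suppressWarnings(ks.test(b_hat[h], -b_hat[-h])$p.value), 0.01)
  # median pinned near zero (the density is high there)
  expect_lt(abs(median(b_hat)), 0.1)
})

test_that("corrected estimator is right-skewed under a positive causal effect", {
  b_hat <- simulate_b_hat(small_cfg(), b = 2)
  expect_gt(mean(b_hat), median(b_hat))
  expect_gt(median(b_hat), 2)  # median exceeds the truth (bias direction)
})

test_that("summary table aggregates coherent proportions and the power ordering", {
  tab <- run_table1(small_cfg(b_values = c(0, 1)))
  expect_s3_class(tab, "simulation_table")
  props <- unlist(tab[, c("support_coverage", "power_T",
                          "ci_coverage", "power_smr")])
  expect_true(all(props >= 0 & props <= 1))
  # the conditional test dominates the SMR test at every b
  expect_true(all(tab$power_T >= tab$power_smr))
  # SMR CI coverage deteriorates with b while the support holds up
  expect_lt(tab$ci_coverage[tab$b == 1], tab$ci_coverage[tab$b == 0])
  expect_true(all(tab$support_coverage > 0.9))
})
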