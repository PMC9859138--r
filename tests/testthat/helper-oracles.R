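# Independent oracles and shared fixtures for the test suite.

# The worked single-SNP example: exposure z-score just above the genome-wide
# threshold, very strong outcome signal.
fig_pair <- function() summary_pair(5.4599, 1, 12.3155, 1, snp_id = "example")

gw_rule <- function() selection_rule(5.45131)

# Inverse-CDF sampler of the two-tail truncated normal: uniform over the
# combined tail mass, mapped through qnorm.  Independent of the closed-form
# moment expressions under test, and usable even when the selection
# probability is tiny (where rejection sampling is infeasible).
rtrunc2_invcdf <- function(n, mu, sigma, tau) {
  a1 <- -tau - mu / sigma
  a2 <- tau - mu / sigma
  p1 <- pnorm(a1)               # lower-tail mass
  p2 <- pnorm(a2)               # cdf at the lower edge of the upper tail
  A <- p1 + (1 - p2)
  u <- runif(n) * A
  z <- ifelse(u <= p1, qnorm(pmin(u, p1)), qnorm(p2 + (u - p1)))
  mu + sigma * z
}

# Rejection sampler: draw plain normals, keep those passing selection, until
# n_accept draws are collected.  Only usable when the acceptance probability
# is non-negligible.
rtrunc2_reject <- function(n_accept, mu, sigma, tau, batch = 2e6) {
  out <- numeric(0)
  while (length(out) < n_accept) {
    z <- rnorm(batch, mu, sigma)
    out <- c(out, z[abs(z) / sigma >= tau])
  }
  out[seq_len(n_accept)]
}

# Monte-Carlo standard error of a sample variance.
se_of_var <- function(z) {
  m <- mean(z)
  sqrt((mean((z - m)^4) - var(z)^2) / length(z))
}

# Random selected pairs for property tests: exposure z-scores drawn from the
# truncated distribution, outcomes normal.
random_selected_pairs <- function(n, mu = 4, tau = 5.45131, b = 1) {
  x <- rtrunc2_invcdf(n, mu, 1, tau)
  y <- rnorm(n, b * mu, 1)
  lapply(seq_len(n), function(i)
    summary_pair(x[i], 1, y[i], 1, snp_id = paste0("p", i)))
}
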