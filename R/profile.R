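# Internal profile-likelihood machinery on raw scalars, so the simulation
# engine can evaluate tens of thousands of profiles without object overhead.

# log Lx(mu) for observed x under selection at tau (vectorized over mu)
loglik_x_raw <- function(mu, x, sigma_x, tau) {
  stats::dnorm(x, mu, sigma_x, log = TRUE) -
    log_selection_prob(mu, sigma_x, tau)
}

# pl(b) = max_mu [ log Lx(mu) + log Ly(b * mu) ].
# b = 0 decouples: the inner maximizer is mu_x_hat exactly.
# Otherwise: multi-start 1-D maximization. The objective can be bimodal (the
# exposure likelihood pulls mu toward mu_x_hat, the outcome likelihood toward
# y/b), so a coarse grid over an interval covering both pulls locates the
# basins and Brent polishing refines the best ones.
pl_value_raw <- function(b, x, y, sigma_x, sigma_y, tau, mu_hat) {
  if (b == 0)
    return(loglik_x_raw(mu_hat, x, sigma_x, tau) +
             stats::dnorm(y, 0, sigma_y, log = TRUE))
  g <- function(mu) loglik_x_raw(mu, x, sigma_x, tau) +
    stats::dnorm(y, b * mu, sigma_y, log = TRUE)
  cand <- c(mu_hat, y / b, tau * sigma_x / 2, -tau * sigma_x / 2, 0, x)
  cand <- cand[is.finite(cand)]
  lo <- min(cand) - 4 * sigma_x
  hi <- max(cand) + 4 * sigma_x
  grid <- sort(unique(c(seq(lo, hi, length.out = 81L), cand)))
  ng <- length(grid)
  v <- g(grid)
  # refine every local maximum of the gridded profile
  loc <- which(v >= c(-Inf, v[-ng]) & v >= c(v[-1L], -Inf))
  best <- max(v)
  for (i in loc) {
    o <- stats::optimize(g, c(grid[max(1L, i - 1L)], grid[min(ng, i + 1L)]),
                         maximum = TRUE, tol = 1e-10)
    if (o$objective > best) best <- o$objective
  }
  # The outcome-likelihood basin around mu = y/b has half-width of order
  # sigma_y / |b| and can fall between grid points when |b| is large; the
  # exposure basin sits at mu_hat.  Polish both in width-matched windows.
  w_yb <- 6 * sigma_y / abs(b)
  for (win in list(c(y / b - w_yb, y / b + w_yb),
                   c(mu_hat - sigma_x, mu_hat + sigma_x))) {
    o <- stats::optimize(g, win, maximum = TRUE, tol = 1e-10)
    if (o$objective > best) best <- o$objective
  }
  best
}

#' Profile log-likelihood of the causal effect
#'
#' `pl(b) = max over mu_x of [ log Lx(mu_x) + log Ly(b * mu_x) ]`, where `Lx`
#' is the truncated-normal likelihood of the selected exposure statistic and
#' `Ly` the normal likelihood of the outcome statistic with its mean
#' constrained to `b * mu_x`.  The profile is maximized at
#' `b_hat = y / mu_x_hat` with maximum `log Lx(mu_x_hat) + log Ly(y)`, and
#' `pl(b_hat) - pl(0) = T / 2 = y^2 / (2 sigma_y^2)` exactly.  As
#' `|b| -> Inf` the profile tends to `log Lx(0) + log Ly(y)` (take
#' `mu_x = y/b -> 0`), which is what makes one or both support limits
#' unbounded for SNPs near the selection threshold.
#'
#' @param b Causal-effect value(s) at which to evaluate the profile.
#' @param pair A [summary_pair()] that passes selection.
#' @param rule A [selection_rule()] or bare numeric `tau`.
#' @return `pl(b)`, vectorized over `b`.
#' @examples
#' p <- summary_pair(5.4599, 1, 12.3155, 1)
#' profile_loglik(c(0, 33.412), p)
#' @export
profile_loglik <- function(b, pair, rule = selection_rule()) {
  rule <- as_selection_rule(rule)
  stop_if_not_selected(pair, rule)
  fit <- fit_mu_x(pair, rule)
  vapply(b, pl_value_raw, numeric(1), x = pair$x, y = pair$y,
         sigma_x = pair$sigma_x, sigma_y = pair$sigma_y,
         tau = rule$tau, mu_hat = fit$mu_x_hat)
}

#' Calibrate the support unit k to a test level
#'
#' The k-unit support excludes 0 exactly when the conditional test `T`
#' exceeds `2k`, so matching a familywise level `alpha` over `n_tests` SNPs
#' (Bonferroni) requires `k` with `Pr(chi-square(1) > 2k) = alpha / n_tests`,
#' i.e. `k = qchisq(1 - alpha/n_tests, 1) / 2 =
#' qnorm(1 - alpha/(2 n_tests))^2 / 2`.  For `alpha = 0.05` and one test
#' `k = 1.92` (the familiar 95 percent calibration); for 84 tests `k = 5.9`.
#'
#' @param alpha Familywise two-sided level, in (0, 1).
#' @param n_tests Number of SNPs tested (Bonferroni denominator), >= 1.
#' @return The support unit `k`.
#' @examples
#' k_from_alpha(0.05)        # 1.92
#' k_from_alpha(0.05, 84)    # 5.9
#' @export
k_from_alpha <- function(alpha, n_tests = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 1)
    stop("'n_tests' must be a positive integer", call. = FALSE)
  stats::qchisq(1 - alpha / n_tests, df = 1) / 2
}

# Locate the boundary of the connected support component containing b_hat on
# one side (dir = -1 lower, +1 upper).  pl_fun(b) must be the profile;
# cut = pl_max - k; pl0 = pl(0) computed exactly; tail = lim pl(b), |b|->Inf.
# Expands geometrically from b_hat; inserts b = 0 as a checkpoint when a step
# would jump across zero (the profile dips near b = 0 whenever T is large, and
# a geometric step can leap over that dip); bisects on the first bracket.
support_boundary <- function(pl_fun, b_hat, cut, pl0, tail, dir,
                             max_doublings = 60L, bisect_iter = 50L) {
  step0 <- 0.1 * max(1, abs(b_hat))
  b_above <- b_hat
  for (m in 0:max_doublings) {
    b_next <- b_hat + dir * step0 * 2^m
    if ((b_above > 0 && b_next <= 0) || (b_above < 0 && b_next >= 0)) {
      # crossing zero: use the exact pl(0) first
      if (pl0 <= cut) { b_below <- 0; b_lo <- b_above
        return(bisect_support(pl_fun, b_lo, b_below, cut, bisect_iter))
      }
      b_above <- 0  # zero is inside the support; keep going
    }
    v <- pl_fun(b_next)
    if (v <= cut)
      return(bisect_support(pl_fun, b_above, b_next, cut, bisect_iter))
    b_above <- b_next
  }
  if (tail > cut)
    list(limit = dir * Inf, bounded = FALSE)
  else {
    warning("support limit not located within the search range ",
            "and not certified unbounded", call. = FALSE)
    list(limit = NA_real_, bounded = FALSE)
  }
}

bisect_support <- function(pl_fun, b_in, b_out, cut, iter) {
  for (i in seq_len(iter)) {
    mid <- (b_in + b_out) / 2
    if (pl_fun(mid) > cut) b_in <- mid else b_out <- mid
  }
  list(limit = (b_in + b_out) / 2, bounded = TRUE)
}

#' k-unit support interval for the causal effect
#'
#' The k-unit support is the set of causal-effect values `b0` whose profile
#' log-likelihood is within `k` units of the maximum:
#' `{ b0 : pl(b_hat) - pl(b0) < k }`.  Because the effective sample size of a
#' single-SNP MR analysis is one, standard asymptotic confidence intervals are
#' unavailable; the support is the evidential interval estimate used instead.
#' `k = 2` corresponds approximately to a 95 percent interval at `b0 = 0`
#' (see [k_from_alpha()]).
#'
#' A limit is certified unbounded when the tail value
#' `log Lx(0) + log Ly(y)` of the profile exceeds `pl(b_hat) - k`; bounded
#' limits are located by geometric expansion followed by bisection.  When the
#' likelihood set is disconnected (the profile re-crosses the cut beyond a
#' bounded limit, which the tail test detects), the connected component
#' containing `b_hat` is reported with a warning.
#'
#' @param pair A [summary_pair()] that passes selection.
#' @param rule A [selection_rule()] or bare numeric `tau`.
#' @param k Support units, positive (default 2).
#' @return An object of class `"support_interval"`: list with `k`, `lower`,
#'   `upper`, `lower_bounded`, `upper_bounded`, `b_hat`, `pl_max`,
#'   `contains_zero`, `tail_value`, and the exposure `fit`.
#' @examples
#' s <- suppressWarnings(support_interval(summary_pair(5.4599, 1, 12.3155, 1)))
#' s$lower          # about 2.141
#' s$upper_bounded  # FALSE: certified unbounded above
#' @export
support_interval <- function(pair, rule = selection_rule(), k = 2) {
  rule <- as_selection_rule(rule)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive number", call. = FALSE)
  stop_if_not_selected(pair, rule)
  fit <- fit_mu_x(pair, rule)
  b_hat <- pair$y / fit$mu_x_hat
  ly_max <- stats::dnorm(pair$y, pair$y, pair$sigma_y, log = TRUE)
  pl_max <- fit$loglik + ly_max
  cut <- pl_max - k
  pl0 <- fit$loglik + stats::dnorm(pair$y, 0, pair$sigma_y, log = TRUE)
  tail <- loglik_x_raw(0, pair$x, pair$sigma_x, rule$tau) + ly_max
  pl_fun <- function(b) pl_value_raw(b, pair$x, pair$y, pair$sigma_x,
                                     pair$sigma_y, rule$tau, fit$mu_x_hat)
  lo <- support_boundary(pl_fun, b_hat, cut, pl0, tail, dir = -1)
  up <- support_boundary(pl_fun, b_hat, cut, pl0, tail, dir = +1)
  if (tail > cut && (lo$bounded || up$bounded))
    warning("profile likelihood re-exceeds the cut in the far tail; ",
            "the support is disconnected and the connected component ",
            "containing b_hat is reported", call. = FALSE)
  tstat <- (pair$y / pair$sigma_y)^2
  structure(list(k = k,
                 lower = lo$limit, upper = up$limit,
                 lower_bounded = lo$bounded, upper_bounded = up$bounded,
                 b_hat = b_hat, pl_max = pl_max,
                 contains_zero = tstat < 2 * k,
                 tail_value = tail, fit = fit, pair = pair, rule = rule),
            class = "support_interval")
}

#' @export
print.support_interval <- function(x, ...) {
  fmt <- function(v, bounded, side) {
    if (bounded) format(v)
    else if (is.na(v)) "?" else if (side == "lower") "-Inf" else "Inf"
  }
  cat(format(x$k), "-unit support for SNP ", x$pair$snp_id, "\n", sep = "")
  cat("  b_hat =", format(x$b_hat), "\n")
  cat("  support: (", fmt(x$lower, x$lower_bounded, "lower"), ", ",
      fmt(x$upper, x$upper_bounded, "upper"), ")",
      if (!x$lower_bounded || !x$upper_bounded) "  [unbounded limit]",
      "\n", sep = "")
  cat("  contains zero:", x$contains_zero, "\n")
  invisible(x)
}
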