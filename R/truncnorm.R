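#' @name truncnorm-model
#' @title Two-tail truncated normal sampling model for a selected exposure statistic
#'
#' @description
#' When an instrument SNP is retained only because its exposure z-score clears
#' a threshold `tau`, the observed exposure effect estimate `x` no longer has
#' a plain normal sampling distribution: it follows the conditional (two-tail
#' truncated) normal `CN(mu_x, sigma_x^2)` given `|x / sigma_x| >= tau`.
#' These functions provide the density, moments, score residual and maximum
#' likelihood estimate of `mu_x` under that model.  With
#' `alpha1 = -tau - mu_x/sigma_x` and `alpha2 = tau - mu_x/sigma_x`, the
#' selection probability is
#' `A = 1 - Phi(alpha2) + Phi(alpha1)`, the conditional density of `x` is
#' `phi((x - mu_x)/sigma_x) / (A * sigma_x)` on `|x/sigma_x| >= tau`, its mean
#' is `mu_x + sigma_x * (phi(alpha2) - phi(alpha1)) / A`, and its variance is
#' `sigma_x^2 * (1 + (alpha2*phi(alpha2) - alpha1*phi(alpha1))/A -
#' ((phi(alpha2) - phi(alpha1))/A)^2)`.
#'
#' All tail probabilities are computed on the log scale: at genome-wide
#' selection `A` can be as small as 5e-8 (and far smaller for `mu_x` deep
#' inside the truncation band), so `1 - pnorm(...)` would lose all relative
#' precision.
NULL

#' Standardized truncation bounds
#'
#' Returns `alpha1 = -tau - mu_x/sigma_x` and `alpha2 = tau - mu_x/sigma_x`,
#' the standardized endpoints of the excluded band. `alpha1 <= alpha2` always,
#' with gap `2 * tau`; when `tau = 0` the two coincide and there is no
#' selection.
#'
#' @param mu_x True SNP-exposure effect (mean of the untruncated normal).
#'   May be a vector.
#' @param sigma_x Positive standard error of the exposure effect estimate.
#' @param rule A [selection_rule()] or bare numeric `tau`.
#' @return Numeric matrix with columns `alpha1`, `alpha2` (one row per
#'   `mu_x`), or a named length-2 vector when `mu_x` is scalar.
#' @examples
#' alpha_bounds(0, 1, selection_rule(2))            # (-2, 2)
#' alpha_bounds(4, 2, selection_rule(0))            # (-2, -2)
#' @export
alpha_bounds <- function(mu_x, sigma_x, rule = selection_rule()) {
  rule <- as_selection_rule(rule)
  if (!is.numeric(sigma_x) || any(sigma_x <= 0))
    stop("'sigma_x' must be positive", call. = FALSE)
  z <- mu_x / sigma_x
  a1 <- -rule$tau - z
  a2 <- rule$tau - z
  if (length(a1) == 1L) c(alpha1 = a1, alpha2 = a2)
  else cbind(alpha1 = a1, alpha2 = a2)
}

# log selection probability, vectorized over mu_x.
# log A = logsumexp( log P(Z >= alpha2), log P(Z <= alpha1) )
log_selection_prob <- function(mu_x, sigma_x, tau) {
  z <- mu_x / sigma_x
  lu <- stats::pnorm(tau - z, lower.tail = FALSE, log.p = TRUE)
  ll <- stats::pnorm(-tau - z, log.p = TRUE)
  m <- pmax(lu, ll)
  # m is finite: at least one tail has probability >= its share of the mass
  m + log1p(exp(pmin(lu, ll) - m))
}

#' Probability that a SNP passes selection
#'
#' `A = Pr(x/sigma_x >= tau) + Pr(x/sigma_x <= -tau)` under
#' `x ~ N(mu_x, sigma_x^2)`.  This is the normalizing constant of the
#' conditional density; `log = TRUE` returns `log A` computed from the
#' complementary tail functions so that tiny selection probabilities retain
#' full relative precision.
#'
#' @inheritParams alpha_bounds
#' @param log Return `log A` instead of `A`.
#' @return Selection probability in `(0, 1]` (or its log), vectorized over
#'   `mu_x`.
#' @examples
#' selection_prob(0, 1, selection_rule(5.45131))   # 5e-8, genome-wide p
#' selection_prob(4, 1, selection_rule(5.45131))   # about 0.0733
#' @export
selection_prob <- function(mu_x, sigma_x, rule = selection_rule(), log = FALSE) {
  rule <- as_selection_rule(rule)
  if (!is.numeric(sigma_x) || any(sigma_x <= 0))
    stop("'sigma_x' must be positive", call. = FALSE)
  la <- log_selection_prob(mu_x, sigma_x, rule$tau)
  if (log) la else exp(la)
}

#' Conditional log-density of the selected exposure statistic
#'
#' Log-density of `x ~ CN(mu_x, sigma_x^2)`:
#' `log phi((x - mu_x)/sigma_x) - log sigma_x - log A`.  Defined only on the
#' support `|x / sigma_x| >= tau`; `x` inside the truncation band is a domain
#' error because the density is zero there.
#'
#' @param x Observed exposure effect estimate(s); must pass selection.
#' @inheritParams alpha_bounds
#' @return Log-density, vectorized over `x` and/or `mu_x`.
#' @export
cond_log_density <- function(x, mu_x, sigma_x, rule = selection_rule()) {
  rule <- as_selection_rule(rule)
  if (!is.numeric(sigma_x) || any(sigma_x <= 0))
    stop("'sigma_x' must be positive", call. = FALSE)
  if (any(abs(x) / sigma_x < rule$tau))
    stop("'x' lies inside the truncation band |x|/sigma_x < tau; ",
         "the conditional density is zero there", call. = FALSE)
  stats::dnorm(x, mean = mu_x, sd = sigma_x, log = TRUE) -
    log_selection_prob(mu_x, sigma_x, rule$tau)
}

# (phi(alpha2) - phi(alpha1)) / A, in log space; vectorized over mu_x.
hazard_diff <- function(mu_x, sigma_x, tau) {
  z <- mu_x / sigma_x
  a1 <- -tau - z
  a2 <- tau - z
  la <- log_selection_prob(mu_x, sigma_x, tau)
  exp(stats::dnorm(a2, log = TRUE) - la) - exp(stats::dnorm(a1, log = TRUE) - la)
}

#' Mean of the truncated exposure statistic
#'
#' `E(x) = mu_x + sigma_x * (phi(alpha2) - phi(alpha1)) / A`.  With `tau = 0`
#' this reduces to `mu_x`.  The observed `x` is unbiased for this conditional
#' mean but biased for `mu_x` itself — the winner's curse.
#'
#' @inheritParams alpha_bounds
#' @return Conditional mean, vectorized over `mu_x`.
#' @export
cond_mean <- function(mu_x, sigma_x, rule = selection_rule()) {
  rule <- as_selection_rule(rule)
  if (!is.numeric(sigma_x) || any(sigma_x <= 0))
    stop("'sigma_x' must be positive", call. = FALSE)
  mu_x + sigma_x * hazard_diff(mu_x, sigma_x, rule$tau)
}

#' Variance of the truncated exposure statistic
#'
#' `Var(x) = sigma_x^2 * (1 + (alpha2 phi(alpha2) - alpha1 phi(alpha1))/A -
#' ((phi(alpha2) - phi(alpha1))/A)^2)`.  Unlike the untruncated model this
#' variance depends on `mu_x`; with `tau = 0` it reduces to `sigma_x^2`.
#'
#' @inheritParams alpha_bounds
#' @return Conditional variance (positive), vectorized over `mu_x`.
#' @export
cond_var <- function(mu_x, sigma_x, rule = selection_rule()) {
  rule <- as_selection_rule(rule)
  if (!is.numeric(sigma_x) || any(sigma_x <= 0))
    stop("'sigma_x' must be positive", call. = FALSE)
  tau <- rule$tau
  z <- mu_x / sigma_x
  a1 <- -tau - z
  a2 <- tau - z
  la <- log_selection_prob(mu_x, sigma_x, tau)
  t1 <- a2 * exp(stats::dnorm(a2, log = TRUE) - la) -
        a1 * exp(stats::dnorm(a1, log = TRUE) - la)
  r <- hazard_diff(mu_x, sigma_x, tau)
  sigma_x^2 * (1 + t1 - r^2)
}

#' Score residual of the conditional likelihood
#'
#' The score equation for `mu_x` under the conditional model sets the
#' observed `x` equal to the conditional mean:
#' `x = mu_x + sigma_x (phi(alpha2) - phi(alpha1)) / A`.  This function
#' returns `x - cond_mean(mu_x)`, whose root in `mu_x` is the MLE.  For a
#' selected `x > 0` the residual at `mu_x = 0` is positive and at `mu_x = x`
#' negative, so the root is bracketed in `(0, x)` (mirrored for `x < 0`).
#'
#' @param mu_x Candidate value(s) of the SNP-exposure effect.
#' @param pair A [summary_pair()] that passes selection.
#' @inheritParams alpha_bounds
#' @return `x - E(x; mu_x)`, vectorized over `mu_x`.
#' @export
score_residual <- function(mu_x, pair, rule = selection_rule()) {
  rule <- as_selection_rule(rule)
  stop_if_not_selected(pair, rule)
  pair$x - cond_mean(mu_x, pair$sigma_x, rule)
}

# Scalar MLE workhorse, free of object plumbing so the simulation engine can
# call it tens of thousands of times.  Returns list(root, iter, converged).
fit_mu_scalar <- function(x, sigma_x, tau,
                          tol = 1e-10 * sigma_x, maxiter = 200L) {
  if (tau == 0) return(list(root = x, iter = 0L, converged = TRUE))
  if (x == 0) stop("x = 0 cannot pass a positive selection threshold",
                   call. = FALSE)
  f <- function(mu) x - mu - sigma_x * hazard_diff(mu, sigma_x, tau)
  eps <- 1e-12 * sigma_x * sign(x)
  out <- tryCatch(
    stats::uniroot(f, lower = min(eps, x), upper = max(eps, x),
                   tol = tol, maxiter = maxiter),
    error = function(e) NULL)
  if (!is.null(out))
    return(list(root = out$root, iter = out$iter, converged = TRUE))
  # Fall back to direct likelihood maximization (log Lx is unimodal in mu_x);
  # multi-start golden-section over [-|x|, |x|].
  obj <- function(mu) stats::dnorm(x, mu, sigma_x, log = TRUE) -
    log_selection_prob(mu, sigma_x, tau)
  starts <- seq(-abs(x), abs(x), length.out = 10L)
  best <- NULL
  for (i in seq_len(length(starts) - 1L)) {
    o <- stats::optimize(obj, c(starts[i], starts[i + 1L]),
                         maximum = TRUE, tol = tol)
    if (is.null(best) || o$objective > best$objective) best <- o
  }
  list(root = best$maximum, iter = maxiter, converged = FALSE)
}

#' Maximum likelihood estimate of the SNP-exposure effect under selection
#'
#' Solves the score equation of the conditional (truncated-normal) likelihood
#' for `mu_x` by a bracketed root search on [score_residual()] over
#' `(0, x)` (mirrored for negative `x`).  The estimate is strictly shrunk
#' toward zero, `0 < |mu_x_hat| < |x|`, is an odd function of `x`, and
#' satisfies the fixed-point identity `cond_mean(mu_x_hat) = x`.  With
#' `tau = 0` there is no selection and the MLE is `x` itself.
#'
#' @param pair A [summary_pair()] that passes selection.
#' @inheritParams alpha_bounds
#' @return An object of class `"truncated_fit"`: a list with `mu_x_hat`, the
#'   maximized conditional log-likelihood `loglik`, `converged`, and
#'   `iterations`.
#' @examples
#' fit <- fit_mu_x(summary_pair(5.4599, 1, 12.3155, 1))
#' fit$mu_x_hat              # about 0.3686: strong shrinkage near threshold
#' @export
fit_mu_x <- function(pair, rule = selection_rule()) {
  rule <- as_selection_rule(rule)
  stop_if_not_selected(pair, rule)
  sol <- fit_mu_scalar(pair$x, pair$sigma_x, rule$tau)
  ll <- if (rule$tau == 0)
    stats::dnorm(pair$x, sol$root, pair$sigma_x, log = TRUE)
  else
    cond_log_density(pair$x, sol$root, pair$sigma_x, rule)
  if (!sol$converged)
    warning("score-equation root search failed; returning the ",
            "golden-section maximizer of the conditional log-likelihood",
            call. = FALSE)
  structure(list(mu_x_hat = sol$root, loglik = ll,
                 converged = sol$converged, iterations = sol$iter,
                 pair = pair, rule = rule),
            class = "truncated_fit")
}

#' @export
print.truncated_fit <- function(x, ...) {
  cat("Truncated-normal MLE for SNP", x$pair$snp_id, "\n")
  cat("  mu_x_hat =", format(x$mu_x_hat),
      " (observed x =", format(x$pair$x), ")\n")
  cat("  log-likelihood =", format(x$loglik),
      " converged:", x$converged, "\n")
  invisible(x)
}
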