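#' Winner's-curse-corrected causal-effect estimate
#'
#' The corrected MLE of the causal effect is `b_hat = y / mu_x_hat`, where
#' `mu_x_hat` is the conditional (truncated-normal) MLE of the SNP-exposure
#' effect.  Because `|mu_x_hat| < |x|`, the naive Wald ratio `y / x`
#' underestimates `b` in absolute value.  The accompanying test of
#' `H0: b = 0` is the conditional likelihood-ratio statistic
#' `T = y^2 / sigma_y^2 ~ chi-square(1)`: the exposure-likelihood terms
#' cancel, so `T` does not depend on `x`, `sigma_x` or `tau`.
#'
#' @param pair A [summary_pair()] that passes selection.
#' @param rule A [selection_rule()] or bare numeric `tau`.
#' @return An object of class `"causal_estimate"`: list with `b_hat`,
#'   `method = "corrected"`, `statistic`, `p_value`, `df = 1`, and the
#'   underlying `fit` (a `"truncated_fit"`).
#' @examples
#' corrected_estimate(summary_pair(5.4599, 1, 12.3155, 1))  # b_hat = 33.41
#' @export
corrected_estimate <- function(pair, rule = selection_rule()) {
  rule <- as_selection_rule(rule)
  fit <- fit_mu_x(pair, rule)
  ct <- conditional_test(pair)
  structure(list(b_hat = pair$y / fit$mu_x_hat, method = "corrected",
                 variance = NA_real_,
                 statistic = ct$statistic, p_value = ct$p_value, df = 1L,
                 fit = fit, pair = pair),
            class = "causal_estimate")
}

#' Conditional likelihood-ratio test of no causal effect
#'
#' `T = 2 log L(mu_x_hat, y) / L(mu_x_hat, 0) = y^2 / sigma_y^2`, referred to
#' chi-square with 1 df.  Valid under instrument selection because the
#' truncated exposure likelihood is the same under the null and the
#' alternative, so it cancels from the ratio.
#'
#' @param pair A [summary_pair()].
#' @return List with `statistic` and `p_value`.
#' @examples
#' conditional_test(summary_pair(6, 1, 1.96, 1))  # statistic 3.8416, p 0.05
#' @export
conditional_test <- function(pair) {
  stat <- (pair$y / pair$sigma_y)^2
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Classical SMR ratio estimate with delta-method variance
#'
#' The summary-data MR estimate `b_smr = y / x` with delta-method variance
#' `V_delta = Var(y)/x^2 + b_smr^2 Var(x)/x^2 = (sigma_y^2 + b_smr^2
#' sigma_x^2) / x^2` (the covariance term is zero across two independent
#' samples), the chi-square test `T_smr = b_smr^2 / V_delta`, and the
#' symmetric Wald interval `b_smr +/- z_{1-alpha/2} sqrt(V_delta)`.  No
#' winner's-curse correction is applied; under instrument selection the Wald
#' interval undercovers increasingly as `b` grows.
#'
#' @param pair A [summary_pair()] with `x != 0`.
#' @param alpha Two-sided non-coverage level of the Wald interval
#'   (default 0.05, a 95 percent CI).
#' @return An object of class `"causal_estimate"`: list with `b_hat`,
#'   `method = "smr"`, `variance`, `statistic`, `p_value`, `df`, `ci_lower`,
#'   `ci_upper`, `conf_level`.
#' @examples
#' smr_estimate(summary_pair(4, 1, 8, 1))  # b_hat = 2, variance = 0.3125
#' @export
smr_estimate <- function(pair, alpha = 0.05) {
  if (pair$x == 0)
    stop("SMR ratio undefined: exposure estimate x is zero", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  b <- pair$y / pair$x
  v <- (pair$sigma_y^2 + b^2 * pair$sigma_x^2) / pair$x^2
  stat <- b^2 / v
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(b_hat = b, method = "smr", variance = v,
                 statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1L,
                 ci_lower = b - z * sqrt(v), ci_upper = b + z * sqrt(v),
                 conf_level = 1 - alpha, pair = pair),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  lab <- if (x$method == "corrected") "Winner's-curse-corrected" else "SMR"
  cat(lab, "estimate for SNP", x$pair$snp_id, "\n")
  cat("  b_hat =", format(x$b_hat), "\n")
  if (x$method == "smr")
    cat("  ", format(100 * x$conf_level), "% CI: (",
        format(x$ci_lower), ", ", format(x$ci_upper), ")\n", sep = "")
  cat("  chi-square(1) statistic =", format(x$statistic),
      " p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Selection-adjusted SMR statistic
#'
#' Replacing `b_smr` by `y / mu_x_hat` and `sigma_x^2` by the truncated
#' variance `sigma_tilde_x^2` (evaluated at `mu_x_hat`) in the SMR statistic
#' gives `T_tilde = y^2 / (sigma_y^2 + sigma_tilde_x^2 * y^2 / mu_x_hat^2)`.
#' This is always strictly smaller than the conditional statistic
#' `T = y^2 / sigma_y^2` whenever `y != 0`, i.e. the adjusted SMR test is
#' less powerful than `T`; it is provided for completeness, not as a
#' recommended test.
#'
#' @inheritParams corrected_estimate
#' @return List with `statistic` and `p_value` (chi-square, 1 df).
#' @export
modified_smr <- function(pair, rule = selection_rule()) {
  rule <- as_selection_rule(rule)
  fit <- fit_mu_x(pair, rule)
  s2 <- cond_var(fit$mu_x_hat, pair$sigma_x, rule)
  stat <- pair$y^2 / (pair$sigma_y^2 + s2 * pair$y^2 / fit$mu_x_hat^2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
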