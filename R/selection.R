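#' Selection rule for an instrument SNP
#'
#' In two-sample summary-data Mendelian randomization the instrument SNP is
#' usually selected from the exposure GWAS because its association z-score
#' clears a significance threshold: `|x| / sigma_x >= tau`.  A
#' `selection_rule` records that threshold `tau` on the z scale.  The default
#' corresponds to genome-wide significance, p = 5e-8 two-sided, i.e.
#' `tau = qnorm(1 - 2.5e-8) = 5.45131`.
#'
#' `tau = 0` means no selection, in which case the conditional sampling model
#' reduces to a plain normal distribution.
#'
#' @param tau Non-negative truncation threshold on the z scale (dimensionless).
#' @return An object of class `"selection_rule"`.
#' @examples
#' selection_rule()            # genome-wide significance
#' selection_rule(tau = 0)     # no selection
#' @export
selection_rule <- function(tau = 5.45131) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("'tau' must be a single non-negative number", call. = FALSE)
  structure(list(tau = as.numeric(tau)), class = "selection_rule")
}

#' @export
print.selection_rule <- function(x, ...) {
  cat("Selection rule: |x| / sigma_x >=", format(x$tau), "\n")
  if (x$tau > 0)
    cat("  (two-sided z threshold; p <=", format(2 * stats::pnorm(-x$tau), digits = 3), ")\n")
  invisible(x)
}

# Accept either a selection_rule or a bare numeric tau.
as_selection_rule <- function(rule) {
  if (inherits(rule, "selection_rule")) return(rule)
  if (is.numeric(rule) && length(rule) == 1L) return(selection_rule(rule))
  stop("'rule' must be a selection_rule or a single numeric tau", call. = FALSE)
}

#' GWAS summary statistics for one SNP
#'
#' The entire data for a single-SNP Mendelian randomization analysis: the
#' estimated SNP effect on the exposure (`x`) with its standard error
#' (`sigma_x`) from the exposure GWAS, and the estimated SNP effect on the
#' outcome (`y`) with its standard error (`sigma_y`) from an independent
#' outcome GWAS.  The standard errors are treated as known constants; their
#' sampling variation is ignored because GWAS sample sizes are very large.
#'
#' @param x Exposure effect estimate (trait units per allele).
#' @param sigma_x Its standard error; must be positive.
#' @param y Outcome effect estimate.
#' @param sigma_y Its standard error; must be positive.
#' @param snp_id Optional SNP label.
#' @return An object of class `"summary_pair"`.
#' @examples
#' summary_pair(x = 5.4599, sigma_x = 1, y = 12.3155, sigma_y = 1)
#' @export
summary_pair <- function(x, sigma_x, y, sigma_y, snp_id = "snp") {
  for (nm in c("x", "sigma_x", "y", "sigma_y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (sigma_x <= 0) stop("'sigma_x' must be positive", call. = FALSE)
  if (sigma_y <= 0) stop("'sigma_y' must be positive", call. = FALSE)
  structure(list(snp_id = as.character(snp_id), x = x, sigma_x = sigma_x,
                 y = y, sigma_y = sigma_y),
            class = "summary_pair")
}

#' @export
print.summary_pair <- function(x, ...) {
  cat("SNP", x$snp_id, ": x =", format(x$x), "(SE", format(x$sigma_x), "),",
      "y =", format(x$y), "(SE", format(x$sigma_y), ")\n")
  invisible(x)
}

#' Does a SNP pass the selection threshold?
#'
#' @param pair A [summary_pair()].
#' @param rule A [selection_rule()] (or a bare numeric `tau`).
#' @return `TRUE` when `|x| / sigma_x >= tau` (closed inequality).
#' @export
is_selected <- function(pair, rule = selection_rule()) {
  rule <- as_selection_rule(rule)
  abs(pair$x) / pair$sigma_x >= rule$tau
}

stop_if_not_selected <- function(pair, rule) {
  if (!is_selected(pair, rule))
    stop(sprintf(
      "SNP '%s' does not pass selection: |x|/sigma_x = %.4f < tau = %.4f",
      pair$snp_id, abs(pair$x) / pair$sigma_x, rule$tau), call. = FALSE)
  invisible(TRUE)
}
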