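#' One-sample individual-level data for instrumental-variable validation
#'
#' Container for centered vectors of genotype scores `g`, exposure `x` and
#' outcome `y` on the same `n` subjects.  Used to validate that the
#' delta-method variance of the ratio estimate equals the classical two-stage
#' least squares (TSLS) variance when no instrument selection takes place.
#'
#' @param g,x_vec,y_vec Numeric vectors of equal length `n >= 3`; each is
#'   centered here if not already (`center = TRUE`), and must be centered to
#'   within 1e-10 otherwise.  `g` must not be constant.
#' @param center Center the three vectors (default `TRUE`).
#' @return An object of class `"individual_sample"`.
#' @export
individual_sample <- function(g, x_vec, y_vec, center = TRUE) {
  n <- length(g)
  if (length(x_vec) != n || length(y_vec) != n)
    stop("'g', 'x_vec' and 'y_vec' must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (center) {
    g <- g - mean(g); x_vec <- x_vec - mean(x_vec); y_vec <- y_vec - mean(y_vec)
  } else {
    if (max(abs(c(mean(g), mean(x_vec), mean(y_vec)))) > 1e-10)
      stop("vectors must be mean-centered (tolerance 1e-10)", call. = FALSE)
  }
  if (sum(g^2) == 0) stop("'g' is constant: not a usable instrument",
                          call. = FALSE)
  structure(list(g = g, x_vec = x_vec, y_vec = y_vec, n = n),
            class = "individual_sample")
}

#' Single-SNP GWAS coefficients and their second-order moments
#'
#' Regression-through-the-origin coefficients of the centered exposure and
#' outcome on the centered genotype, `b_gx = g'x / g'g` and
#' `b_gy = g'y / g'g`, with moment estimates
#' `Var(b_gx) = n^{-1} x'(I-P)x / g'g`, `Var(b_gy) = n^{-1} y'(I-P)y / g'g`
#' and `Cov(b_gx, b_gy) = n^{-1} x'(I-P)y / g'g`, where `P = g g' / g'g`.
#' The covariance is generally non-zero on one-sample data, which is why the
#' two-sample SMR variance (which drops it) cannot be used there.
#'
#' @param sample An [individual_sample()].
#' @return List with `b_gx`, `b_gy`, `var_gx`, `var_gy`, `cov_gxgy`.
#' @export
gwas_coefs <- function(sample) {
  stopifnot(inherits(sample, "individual_sample"))
  g <- sample$g; x <- sample$x_vec; y <- sample$y_vec; n <- sample$n
  gg <- sum(g^2)
  b_gx <- sum(g * x) / gg
  b_gy <- sum(g * y) / gg
  rx <- x - g * b_gx   # (I - P) x
  ry <- y - g * b_gy   # (I - P) y
  list(b_gx = b_gx, b_gy = b_gy,
       var_gx = sum(rx * rx) / (n * gg),
       var_gy = sum(ry * ry) / (n * gg),
       cov_gxgy = sum(rx * ry) / (n * gg))
}

#' Two-stage least squares fit with one instrument
#'
#' `b_tsls = x'Py / x'Px = b_gy / b_gx` (identical to the ratio estimate),
#' with the classical TSLS variance
#' `v_tsls = n^{-1} (y - b x)'(y - b x) / (x'Px)`.  On one-sample data this
#' variance equals the full delta-method variance of the ratio (including its
#' covariance term) exactly — the identity this module exists to verify.
#'
#' @param sample An [individual_sample()] with `g'x != 0`.
#' @return List with `b_tsls` and `v_tsls`.
#' @export
tsls_fit <- function(sample) {
  stopifnot(inherits(sample, "individual_sample"))
  g <- sample$g; x <- sample$x_vec; y <- sample$y_vec; n <- sample$n
  gg <- sum(g^2)
  gx <- sum(g * x)
  if (gx == 0)
    stop("instrument is orthogonal to the exposure: TSLS undefined",
         call. = FALSE)
  b <- sum(g * y) / gx                 # = b_gy / b_gx
  r <- y - b * x
  xPx <- gx^2 / gg
  list(b_tsls = b, v_tsls = sum(r * r) / (n * xPx))
}

#' Simulate confounded one-sample instrumental-variable data
#'
#' Structural model: `x = b_gx g + e_x`, `y = b x + u + e_y`, with the
#' exposure noise `e_x` correlated with the unobserved confounder `u`
#' (correlation strength `conf`), so that naive regression of `y` on `x` is
#' biased but the instrument identities still hold.  The genotype is a
#' centered binomial(2, maf) allele count.
#'
#' @param n Sample size.
#' @param b_gx SNP-exposure effect (default 0.5).
#' @param b Causal effect of exposure on outcome (default 1).
#' @param conf Confounding strength: weight of `u` inside `e_x`
#'   (default 0.5).
#' @param maf Minor allele frequency of the instrument (default 0.3).
#' @param sd_y SD of the outcome noise `e_y` (default 1).
#' @return An [individual_sample()].
#' @export
simulate_iv_sample <- function(n, b_gx = 0.5, b = 1, conf = 0.5,
                               maf = 0.3, sd_y = 1) {
  g <- stats::rbinom(n, 2L, maf)
  u <- stats::rnorm(n)
  e_x <- conf * u + stats::rnorm(n, sd = sqrt(max(0, 1 - conf^2)))
  x <- b_gx * g + e_x
  y <- b * x + u + stats::rnorm(n, sd = sd_y)
  individual_sample(g, x, y)
}
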