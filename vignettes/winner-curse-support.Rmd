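---
title: "Correcting the winner's curse in single-SNP summary-data Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting the winner's curse in single-SNP summary-data Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcmr)
```

## The problem

Two-sample summary-data Mendelian randomization (MR) estimates the causal
effect $b$ of an exposure on an outcome from four numbers per instrument SNP:
the SNP-exposure effect estimate $x$ with standard error $\sigma_x$ from the
exposure GWAS, and the SNP-outcome effect estimate $y$ with standard error
$\sigma_y$ from an independent outcome GWAS.  The popular SMR method uses the
ratio $\hat b_{SMR} = y/x$ with delta-method variance
$V_\Delta = (\sigma_y^2 + \hat b_{SMR}^2\sigma_x^2)/x^2$.

In practice the instrument is *selected from the exposure GWAS itself* —
typically at genome-wide significance, $|x|/\sigma_x \ge \tau$ with
$\tau = 5.45131$ (two-sided $p \le 5\times10^{-8}$).  Conditional on being
selected, $x$ no longer has a plain normal sampling distribution: its
magnitude is inflated (the winner's curse), so $y/x$ is biased toward zero
and the Wald confidence interval undercovers, increasingly so as $b$ grows.

## The conditional model and the corrected estimate

This package models the selected exposure statistic by the two-tail
truncated normal $x \sim CN(\mu_x, \sigma_x^2)$ given
$|x/\sigma_x| \ge \tau$, while $y \sim N(b\,\mu_x, \sigma_y^2)$ is untouched
by the selection.  With $\alpha_1 = -\tau - \mu_x/\sigma_x$,
$\alpha_2 = \tau - \mu_x/\sigma_x$ and selection probability
$A = 1 - \Phi(\alpha_2) + \Phi(\alpha_1)$, the conditional mean of $x$ is

$$E(x) = \mu_x + \frac{\sigma_x}{A}\left[\phi(\alpha_2) - \phi(\alpha_1)\right],$$

and the score equation of the conditional likelihood sets the observed $x$
equal to this mean.  Its root $\hat\mu_x$ (`fit_mu_x()`) is strictly shrunk:
$0 < \hat\mu_x < x$ for $x > 0$, mirrored for $x < 0$.  The corrected causal
estimate is $\hat b = y/\hat\mu_x$ (`corrected_estimate()`), and the
likelihood-ratio test of $H_0: b = 0$ collapses to the *conditional test*
$T = y^2/\sigma_y^2 \sim \chi^2_1$ (`conditional_test()`), because the
exposure likelihood is the same under null and alternative.

Shrinkage matters most for SNPs near the threshold: at
$x/\sigma_x = 5.4599$ the MLE is $\hat\mu_x = 0.369$, a twelve-fold
correction, while at $x/\sigma_x = 8$ the gap $x - \hat\mu_x$ is below
0.02.  Exact computation puts the gap at $x/\sigma_x = 7.5$ at 0.0561,
dropping below 0.05 just above 7.55 — SNPs beyond that point are barely
affected by the curse.

## Support intervals instead of confidence intervals

One SNP contributes a single "observation", so asymptotic likelihood theory
does not apply and the profile likelihood ratio has no usable reference
distribution away from $b_0 = 0$.  The interval estimate is therefore a
*k-unit support* (`support_interval()`): the set of $b_0$ with

$$pl(\hat b) - pl(b_0) < k, \qquad
pl(b) = \max_{\mu_x}\left[\log L_x(\mu_x) + \log L_y(b\,\mu_x)\right].$$

The profile is maximized at $\hat b = y/\hat\mu_x$, and
$pl(\hat b) - pl(0) = T/2$ exactly, so the k-unit support excludes zero
precisely when $T > 2k$.  `k_from_alpha()` exploits this duality to
calibrate $k$ to a familywise level: $k = q_{\chi^2_1}(1-\alpha/m)/2$, giving
the familiar $k = 1.92 \approx 2$ for a single test at $\alpha = 0.05$ and
$k = 5.9$ for 84 SNPs under Bonferroni.

As $|b| \to \infty$ the profile tends to $\log L_x(0) + \log L_y(y)$ (set
$\mu_x = y/b \to 0$).  For weak instruments this tail value can exceed
$pl(\hat b) - k$, in which case a support limit is genuinely unbounded — the
data cannot rule out arbitrarily large effects.  The package certifies
unboundedness by this tail test rather than guessing from where a numeric
search stopped.

## Numerical choices

* **Log-space tails.** $A$ is as small as $5\times10^{-8}$ at $\mu_x = 0$
  and vanishes double-exponentially inside the truncation band, so $\log A$
  is computed by log-sum-exp over `pnorm(..., log.p = TRUE)` tail calls, and
  every density ratio is assembled in log space.  `1 - pnorm(...)` would
  lose all relative precision exactly where the model lives.
* **MLE solver.** The score residual changes sign over $(0, x)$ (a
  consequence of the sign of $\phi(\alpha_2)-\phi(\alpha_1)$), so the root
  is bracketed and solved with `uniroot` at tolerance $10^{-10}\sigma_x$,
  200 iterations; a multi-start golden-section maximization of the
  conditional log-likelihood is the fallback if bracketing ever fails.
  Worked-example values in the documentation are frozen from this solver and
  independently confirmed by 40-digit arithmetic.
* **Inner profile maximization.** For fixed $b$ the objective
  $\log L_x(\mu) + \log L_y(b\mu)$ can be bimodal: the exposure term pulls
  $\mu$ toward $\hat\mu_x$, the outcome term toward $y/b$.  The maximizer is
  found by refining every local maximum of an 81-point grid spanning all
  candidate basins, plus width-matched Brent polishing around $\hat\mu_x$
  and around $y/b$ — the outcome basin has half-width of order
  $\sigma_y/|b|$ and would otherwise slip between grid points at large
  $|b|$.  $pl(0)$ is computed exactly ($\mu_x$ decouples), never numerically.
* **Support boundaries.** Each limit is found by geometric expansion from
  $\hat b$ in steps $0.1\max(1,|\hat b|)\cdot 2^m$ followed by 50 bisection
  steps.  Because the profile dips near $b = 0$ whenever $T$ is large, a
  step that would jump across zero first checks the exact $pl(0)$, so the
  dip cannot be leapt over.  When the tail test shows the likelihood set is
  disconnected (it re-exceeds the cut beyond a bounded limit), the connected
  component containing $\hat b$ is reported with a warning; the paper-style
  single-interval report is kept, but coverage in the simulation engine uses
  the defining inequality $pl(b_{true}) > pl(\hat b) - k$ directly, which is
  component-agnostic and needs no boundary search.
* **Threshold convention.** $|x|/\sigma_x = \tau$ exactly counts as
  selected (closed inequality), and $\tau = 0$ reduces every formula to the
  no-selection normal model.

## The simulation engine and what it does (not) show

`run_table1()` reproduces the coverage/power comparison: per causal effect
$b$ it draws 100,000 exposure statistics $x \sim N(4, 1)$, keeps the
$\approx 7.3\%$ with $|x| \ge 5.45131$, pairs each with an independent
$y \sim N(4b, 1)$, and summarizes the corrected estimator (mean, median,
2-unit support coverage, power of $T$) against SMR (mean, median, 95% Wald
CI coverage, power).  These defaults are the reference study conditions:
$\mu_x = 4$ makes selection non-trivial but not hopeless, and unit standard
errors put everything on the z scale.  One master seed drives per-$b$
substreams (offset by $100b$), so runs are reproducible and adding a $b$
value never perturbs the others; exposure draws are redrawn per $b$ rather
than recycled, matching independent replication of the whole design.

The generator emulates exactly the model the method assumes: a single SNP,
normal summary statistics with *known* standard errors, non-overlapping
samples, selection applied to the same statistic that is analyzed.  Passing
tests therefore demonstrate internal correctness and calibration under
those assumptions — not robustness to overlapping GWAS samples, to LD
between instruments, to effect-allele misharmonization, or to weak-instrument
non-normality, none of which the generator produces.  Mean summaries of
$\hat b = y/\hat\mu_x$ are heavy-tailed (because $\hat\mu_x$ can be
arbitrarily close to 0) and are reported for completeness; medians and
coverages are the stable quantities.

Problem sizes used in the shipped tests: 100,000 draws per $b$ for the
coverage study, $10^6$ draws for the moment-oracle checks, 1,000 simulated
one-sample datasets (n of 10 to 1,000) for the TSLS-variance identity.

## Design choices where the method left room

* The support/test duality is implemented as "the support *excludes* zero
  iff $T$ exceeds the matched $\chi^2_1$ cutoff", the direction consistent
  with both the duality algebra and the multiple-testing workflow.
* The selection-adjusted SMR statistic (`modified_smr()`), which replaces
  $\sigma_x^2$ by the truncated variance, is implemented for completeness
  but never surfaced as a default: it is dominated by $T$ whenever
  $y \neq 0$.
* In the Bonferroni workflow (`run_analysis(adjust = "bonferroni")`) the
  multiplicity denominator is the number of *selected* SNPs in the input
  table — LD pruning is upstream of this package.
* The one-sample module keeps the covariance term of the delta-method
  variance; the two-sample estimators drop it (independent samples), which
  is what makes the SMR variance computable from summary data at all.

## Known limitations

Non-overlapping exposure and outcome samples are assumed; overlap changes
the joint likelihood and is not handled.  The analysis is per-SNP: no IVW,
MR-Egger or other multi-SNP combination, and no heterogeneity tests.
Standard errors are treated as known constants.  Binary outcomes are
handled only through the usual normal approximation to their GWAS
coefficients.  Support limits for near-threshold SNPs are frequently
unbounded — that is a property of the likelihood, reported honestly, not a
numerical failure.
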