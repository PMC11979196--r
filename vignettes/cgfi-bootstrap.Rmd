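---
title: "Corrected GFI and bootstrap fit evaluation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corrected GFI and bootstrap fit evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgfiboot)
```

## The model and its discrepancy functions

A confirmatory factor model explains `k` observed indicators by `m` latent
factors: `Sigma(theta) = Lambda Phi Lambda' + Theta`, with loadings
`Lambda`, factor covariance `Phi` and diagonal uniquenesses `Theta`. Two
identification conventions are supported and are fit-equivalent: unit
factor variances (all loadings free; the default) or first loading fixed
at 1 (factor variances free). Cross-loadings, correlated residuals,
regressions among latents and mean structures are deliberately out of
scope: the engine targets pure measurement models, and anything else is
rejected at parse time rather than silently mis-fitted.

For continuous data the sample moment is the covariance matrix `S`
(maximum-likelihood divisor `N` by default, `N-1` available) and the
default discrepancy is normal-theory ML,

```
F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - k ,
```

with GLS (`F = 1/2 tr[((S - Sigma) S^-1)^2]`) as an alternative. For
ordered-categorical data the moments are per-item thresholds plus the
polychoric correlation matrix, the model is parameterized in the latent
response metric with implied variances fixed at 1 (delta convention:
uniquenesses are `1 - communality`, not free), and the discrepancy is
weighted least squares on the non-redundant moments: ULS (identity
weights), DWLS (inverse asymptotic variances) or WLS (full inverse
asymptotic covariance). Robust "mean- and variance-adjusted" test-statistic
scalings are not implemented; requesting them is an error rather than a
silent approximation.

Degrees of freedom count non-redundant moments minus free parameters:
`k(k+1)/2 - p` in the covariance metric and `k(k-1)/2 + #thresholds - p`
in the correlation + threshold metric. A 7-indicator one-factor continuous
model therefore has `28 - 14 = 14` df; a 14-indicator one-factor model on
4-category items has `91 + 42 - 56 = 77` df.

## The corrected GFI

The GFI measures the proportion of moment information the model reproduces
(`1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]` under ML/GLS; the
unweighted residual form `1 - tr[(S - Sigma)^2] / tr[S^2]` under
least-squares estimation, where the host metric is already a correlation).
It is biased downward in small samples. The corrected index adds a
deterministic, df-based term:

```
CGFI = GFI + 2 (1 - 2 df / (k (k + 1))) / N .
```

In the covariance metric, where `df = k(k+1)/2 - p`, the correction equals
`4p / (k(k+1) N)`: proportional to the number of free parameters, inversely
proportional to N. We treat the df-based form as normative in every metric;
in the ordinal metric the parameter total includes thresholds and the
`4p` form would differ (the equivalent count there is `k(k+1)/2 - df`).
A raw CGFI above 1 — possible for near-saturated models at small N — is
capped at 1 with a logged note, keeping the index on its natural scale.

The remaining battery follows standard definitions: AGFI
(`1 - [k(k+1)/(2 df)](1 - GFI)`), noncentrality-based CFI and TLI against
the independence baseline (`df_B = k(k-1)/2`; baseline chi-square has a
closed form under ML), `RMSEA = sqrt(max(chi2 - df, 0)/(df N))`, SRMR with
residuals standardized by the sample standard deviations over the lower
triangle including the diagonal (so correlation-metric fits contribute
zero diagonal terms), and AIC/BIC from the ML log-likelihood only —
least-squares estimators have no likelihood and report `NA`. TLI is
reported unclipped (values slightly above 1 are informative); CFI carries
only its max-protection. When the baseline itself fits (`chi2_B <= df_B`),
CFI is 1 and TLI is undefined.

## Estimation choices

* **Optimizer.** L-BFGS-B with analytic gradients for every estimator;
  uniquenesses and factor variances are bounded below at `1e-4`, factor
  correlations at `|rho| <= 0.999`. Up to 5 jittered restarts on
  non-convergence, drawn from the caller's RNG stream so fits are
  reproducible under a set seed. A fit where a variance bound (or the
  ordinal unit-communality cap, enforced by a smooth barrier) binds is
  flagged as a Heywood case with a warning.
* **Chi-square multiplier.** `chi2 = N x F_min` by default (`N-1`
  configurable). With the divisor-N covariance this is the conventional
  pairing; the calibration simulations below confirm `E[chi2] ~ df`.
* **Polychorics.** Two-step: thresholds from the univariate margins
  (`qnorm` of cumulative proportions), then each pairwise correlation by
  maximizing the contingency-table likelihood under the bivariate normal,
  bounded away from ±1 by `1e-4`. The bivariate CDF uses an adaptive
  single-integral (angular) form accurate to ~1e-10. A pairwise-assembled
  matrix with an eigenvalue below `1e-8` is smoothed to the nearest
  unit-diagonal PSD matrix by eigenvalue clipping, and flagged.
* **DWLS/WLS weights.** Asymptotic (co)variances of the polychoric
  estimates come from case-level influence functions, with the score of
  each table cell obtained from the derivative of cell probabilities with
  respect to the correlation (a bivariate-density difference at the cell
  corners). The full WLS weight matrix is the empirical covariance of
  those influence functions, limited to `k <= 25` to avoid its quadratic
  blow-up; thresholds are fitted exactly at their sample values, so the
  weight matrix applies to the correlation block.
* **Missing data.** Listwise deletion only, with the deletion count
  logged. In the bootstrap, raw rows are resampled first and deletion is
  re-applied within each replicate, keeping the resampling unit equal to
  the observed case.

## The bootstrap layer

Each of the `B` replicates (default 1,000) draws `n_raw` rows with
replacement, recomputes moments, refits target and baseline, and
recomputes all indices. Replicates that fail — non-convergence, a
degenerate moment matrix, too few complete rows — are counted and excluded
from summaries; exactly `B` attempts are made, with no retries, since
retrying would bias the distribution toward easy resamples. If more than
half fail, the result is marked unstable with a hard warning. Summaries
are the mean, the sample SD (divisor `B_success - 1`) and percentile
2.5/97.5 bounds using the median-unbiased quantile definition
(Hyndman–Fan type 8). Every replicate runs on a seed substream derived
from one master seed, so results are independent of execution order and
bit-identical across runs. Indices undefined in every replicate (AIC/BIC
under least-squares estimators) summarize as mean `NaN` with `NA` spread,
and render as `NA` in reports.

## What the synthetic generator does and does not emulate

`population_model()` / `generate_continuous()` draw exact multivariate
normal data from `Sigma0 = Lambda Phi Lambda' + Theta`;
`generate_ordinal()` discretizes latent responses at fixed thresholds;
`inject_missing()` adds MCAR missingness. The default scenarios mirror the
two reference shapes used throughout the documentation: a 7-indicator
one-factor scale with loadings 0.7 around N = 200, and a 14-indicator
4-category ordinal scale at large N. Real questionnaire data differ in
ways the generator deliberately ignores: non-normal continuous responses,
missingness that depends on the respondent, minor cross-loadings and
residual correlations. Passing tests therefore certify the arithmetic and
the sampling machinery, not robustness to those violations.

## Problem sizes and a documented limitation

The test suite exercises: 500 Monte-Carlo fits at N = 200 for chi-square
calibration (mean ~14.5 on 14 df, 5.8% rejection at the nominal 5% level),
parameter recovery at N = 100,000 (loadings within 0.01), polychoric
recovery at N = 2,000 (within 0.03), B = 1,000 bootstrap determinism, and
agreement with an independently coded brute-force optimizer on 20 random
problems (relative differences below 1e-3; observed ~1e-6).

One calibration experiment fails by design of the index, and we keep it
failing rather than weaken it: at n = 500 (k = 7, true model), the 95%
percentile bootstrap interval for CGFI almost never contains the
large-sample (N = 100,000) reference value. The reason is structural. The
GFI's downward sampling bias at n = 500 is of order `(k+1)/n ~ 0.016`,
an order of magnitude larger than the CGFI correction `4p/(k(k+1)n) ~
0.003`, and the bootstrap distribution is shifted further downward still —
the same double-bias visible whenever bootstrap means sit below original
estimates in small samples. A percentile interval of a downward-biased
statistic cannot cover a nearly unbiased reference. This is useful to know
when interpreting output: the intervals quantify instability, and for
GFI-family indices in small samples they should be read as pessimistic
bounds, not as unbiased coverage statements.
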