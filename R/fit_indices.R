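# Descriptive fit-index battery and the corrected goodness-of-fit index.

#' Goodness-of-fit index (GFI)
#'
#' Proportion of observed moment information reproduced by the model. For
#' normal-theory estimators (ML/GLS) the classic form
#' `GFI = 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]` is used; for
#' least-squares fits on correlation matrices the unweighted form
#' `GFI = 1 - tr[(S - Sigma)^2] / tr[S^2]`.
#'
#' @param S Sample covariance or correlation matrix.
#' @param Sigma Implied matrix.
#' @param estimator Estimator name; chooses the ML or least-squares form.
#' @return Scalar GFI.
#' @export
compute_gfi <- function(S, Sigma, estimator = "ML") {
  if (estimator %in% c("ML", "GLS")) {
    cZ <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(cZ)) stop("implied matrix is singular", call. = FALSE)
    Q <- chol2inv(cZ) %*% S
    1 - sum((Q - diag(ncol(S)))^2) / sum(Q^2)
  } else {
    1 - sum((S - Sigma)^2) / sum(S^2)
  }
}

#' Adjusted goodness-of-fit index (AGFI)
#'
#' `AGFI = 1 - [k(k+1) / (2 df)] (1 - GFI)`: the GFI penalized for the
#' degrees of freedom the model consumes.
#'
#' @param gfi GFI value.
#' @param k Number of observed variables.
#' @param df Model degrees of freedom (`NA` returned when `df == 0`).
#' @return Scalar AGFI, or `NA` for a saturated model.
#' @export
compute_agfi <- function(gfi, k, df) {
  if (df == 0) return(NA_real_)
  1 - (k * (k + 1) / (2 * df)) * (1 - gfi)
}

#' Corrected goodness-of-fit index (CGFI)
#'
#' Adds to the GFI a correction for small-sample downward bias that also
#' accounts for model complexity:
#' `CGFI = GFI + 2 (1 - 2 df / (k(k+1))) / N`,
#' equivalently `GFI + 4p / (k(k+1) N)` with `p` the number of free
#' parameters (since `df = k(k+1)/2 - p`). The correction vanishes as N
#' grows and shrinks as df approaches the saturated bound. A raw value
#' above 1 is capped at 1 with a warning (attribute `capped`).
#'
#' @param gfi GFI value.
#' @param k Number of observed variables.
#' @param df Model degrees of freedom.
#' @param n Sample size.
#' @return Scalar CGFI (capped at 1).
#' @export
#' @examples
#' compute_cgfi(0.945, k = 7, df = 14, n = 193)  # ~0.950
compute_cgfi <- function(gfi, k, df, n) {
  stopifnot(n >= 1, df >= 0, df <= k * (k + 1) / 2)
  raw <- gfi + 2 * (1 - 2 * df / (k * (k + 1))) / n
  if (raw > 1) {
    warning("CGFI exceeded 1 and was capped", call. = FALSE)
    return(structure(1, capped = TRUE, raw = raw))
  }
  raw
}

#' Incremental fit indices CFI and TLI
#'
#' Noncentrality-based comparison of the target model against the
#' independence baseline:
#' `CFI = 1 - max(chi_T - df_T, 0) / max(chi_B - df_B, chi_T - df_T, 0)`;
#' `TLI = [(chi_B/df_B) - (chi_T/df_T)] / [(chi_B/df_B) - 1]`.
#' When the baseline itself fits (`chi_B <= df_B`), CFI is 1 and TLI is
#' undefined (`NA`).
#'
#' @param chi_t,df_t Target-model chi-square and df.
#' @param chi_b,df_b Baseline-model chi-square and df (`df_b > 0`).
#' @return Named list with `cfi` and `tli`.
#' @export
compute_cfi_tli <- function(chi_t, df_t, chi_b, df_b) {
  stopifnot(df_b > 0)
  nc_t <- chi_t - df_t
  nc_b <- chi_b - df_b
  if (nc_b <= 0) {
    return(list(cfi = 1, tli = NA_real_))
  }
  cfi <- 1 - max(nc_t, 0) / max(nc_b, nc_t, 0)
  tli <- if (df_t == 0) NA_real_ else {
    ((chi_b / df_b) - (chi_t / df_t)) / ((chi_b / df_b) - 1)
  }
  list(cfi = cfi, tli = tli)
}

#' Root mean squared error of approximation (RMSEA)
#'
#' `RMSEA = sqrt(max(chi - df, 0) / (df n))`.
#'
#' @param chi Chi-square statistic.
#' @param df Model degrees of freedom (`NA` returned when 0).
#' @param n Sample size.
#' @return Scalar RMSEA.
#' @export
compute_rmsea <- function(chi, df, n) {
  if (df == 0) return(NA_real_)
  sqrt(max(chi - df, 0) / (df * n))
}

#' Standardized root mean squared residual (SRMR)
#'
#' Residuals are standardized by the sample standard deviations,
#' `(s_ij - sigma_ij) / sqrt(s_ii s_jj)`, and averaged (root mean square)
#' over the `k(k+1)/2` lower-triangle cells including the diagonal. For
#' correlation-metric fits both diagonals are 1, so the diagonal terms
#' contribute zeros.
#'
#' @param S Sample matrix.
#' @param Sigma Implied matrix.
#' @return Scalar SRMR.
#' @export
compute_srmr <- function(S, Sigma) {
  d <- sqrt(diag(S))
  Dinv <- 1 / tcrossprod(d)
  resid <- (S - Sigma) * Dinv
  cells <- resid[lower.tri(resid, diag = TRUE)]
  sqrt(mean(cells^2))
}

#' Information criteria from an ML fit
#'
#' `AIC = -2 loglik + 2 p`; `BIC = -2 loglik + p log(n)`. Only defined for
#' maximum-likelihood fits; least-squares estimators have no likelihood and
#' report `NA`.
#'
#' @param loglik Log-likelihood (or `NULL` for non-ML fits).
#' @param p_free Number of free parameters.
#' @param n Sample size.
#' @return Named list with `aic` and `bic` (both `NA` when `loglik` is
#'   `NULL`).
#' @export
compute_aic_bic <- function(loglik, p_free, n) {
  if (is.null(loglik) || is.na(loglik)) {
    return(list(aic = NA_real_, bic = NA_real_))
  }
  list(aic = -2 * loglik + 2 * p_free,
       bic = -2 * loglik + p_free * log(n))
}

#' Full fit-index battery for a fitted model
#'
#' Combines a target fit, its baseline and the sample moments into the
#' 12-row index set the report prints: chi-square, df, p-value, CFI, TLI,
#' GFI, AGFI, RMSEA, SRMR, AIC, BIC and CGFI.
#'
#' @param fitted A `cgfi_fit` from [fit_cfa()].
#' @param baseline A `cgfi_fit` from [fit_baseline()].
#' @param moments The `cgfi_moments` both were fitted to.
#' @return An object of class `cgfi_indices`: named list of scalars plus
#'   `k`, `p_free` and `n`.
#' @export
fit_index_set <- function(fitted, baseline, moments) {
  stopifnot(inherits(fitted, "cgfi_fit"), inherits(baseline, "cgfi_fit"))
  S <- moments$matrix
  k <- ncol(S)
  n <- fitted$n_effective
  p_free <- fitted$template$p_free
  gfi <- compute_gfi(S, fitted$implied, fitted$estimator)
  inc <- compute_cfi_tli(fitted$chi_square, fitted$df,
                         baseline$chi_square, baseline$df)
  ic <- compute_aic_bic(fitted$loglik, p_free, n)
  cgfi <- compute_cgfi(gfi, k, fitted$df, n)
  structure(
    list(chi_square = fitted$chi_square, df = fitted$df,
         p_value = fitted$p_value, cfi = inc$cfi, tli = inc$tli,
         gfi = gfi, agfi = compute_agfi(gfi, k, fitted$df),
         rmsea = compute_rmsea(fitted$chi_square, fitted$df, n),
         srmr = compute_srmr(S, fitted$implied),
         aic = ic$aic, bic = ic$bic, cgfi = as.numeric(cgfi),
         cgfi_capped = isTRUE(attr(cgfi, "capped")),
         k = k, p_free = p_free, n = n),
    class = "cgfi_indices"
  )
}

# Canonical order and labels of the report rows.
index_names <- function() {
  c(chi_square = "Chi-Square", df = "DF", p_value = "P-Value",
    cfi = "CFI", tli = "TLI", gfi = "GFI", agfi = "AGFI",
    rmsea = "RMSEA", srmr = "SRMR", aic = "AIC", bic = "BIC",
    cgfi = "CGFI")
}

#' @export
print.cgfi_indices <- function(x, digits = 3, ...) {
  nm <- index_names()
  vals <- vapply(names(nm), function(f) {
    v <- x[[f]]
    if (is.null(v) || is.na(v)) "NA" else formatC(v, digits = digits,
                                                  format = "f")
  }, character(1))
  cat(paste(format(nm, width = 10), vals, collapse = "\n"), "\n")
  invisible(x)
}
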