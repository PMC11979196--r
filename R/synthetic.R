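# Synthetic factor-model data: multivariate-normal draws from a known
# population structure and their ordinal discretization, so the estimator,
# index and bootstrap layers are testable end to end without external data.

#' Define a population factor model
#'
#' @param loadings Named list, one element per factor: a named numeric
#'   vector of loadings (names = indicator names).
#' @param factor_correlations Factor correlation matrix (identity by
#'   default).
#' @param uniquenesses Named numeric vector of unique variances; default
#'   `1 - communality`, which makes the population covariance a correlation
#'   matrix.
#' @param thresholds Optional named list of strictly ascending threshold
#'   vectors (ordinal generation only).
#' @return An object of class `cgfi_population`.
#' @export
#' @examples
#' population_model(list(F = stats::setNames(rep(0.7, 7), paste0("x", 1:7))))
population_model <- function(loadings, factor_correlations = NULL,
                             uniquenesses = NULL, thresholds = NULL) {
  stopifnot(is.list(loadings), length(loadings) >= 1L)
  factors <- names(loadings)
  if (is.null(factors) || any(!nzchar(factors))) {
    stop("loadings must be a named list (factor names)", call. = FALSE)
  }
  indicators <- unlist(lapply(loadings, names), use.names = FALSE)
  if (is.null(indicators) || anyDuplicated(indicators)) {
    stop("each loading vector must have unique, named indicators",
         call. = FALSE)
  }
  k <- length(indicators)
  nf <- length(factors)
  Phi <- if (is.null(factor_correlations)) diag(nf) else factor_correlations
  stopifnot(nrow(Phi) == nf, ncol(Phi) == nf)
  Lambda <- matrix(0, k, nf, dimnames = list(indicators, factors))
  for (f in factors) Lambda[names(loadings[[f]]), f] <- loadings[[f]]
  communality <- diag(Lambda %*% Phi %*% t(Lambda))
  if (is.null(uniquenesses)) {
    if (any(communality >= 1)) {
      stop("default uniquenesses need communalities < 1", call. = FALSE)
    }
    uniquenesses <- stats::setNames(1 - communality, indicators)
  } else {
    uniquenesses <- uniquenesses[indicators]
    if (any(is.na(uniquenesses)) || any(uniquenesses < 0)) {
      stop("uniquenesses must be named, complete and >= 0", call. = FALSE)
    }
  }
  if (!is.null(thresholds)) {
    missing_t <- setdiff(indicators, names(thresholds))
    if (length(missing_t)) {
      stop("thresholds missing for: ", paste(missing_t, collapse = ", "),
           call. = FALSE)
    }
    bad <- vapply(thresholds[indicators],
                  function(t) any(diff(t) <= 0), logical(1))
    if (any(bad)) stop("thresholds must be strictly ascending", call. = FALSE)
  }
  structure(
    list(Lambda = Lambda, Phi = Phi,
         uniquenesses = uniquenesses, thresholds = thresholds,
         factors = factors, indicators = indicators, k = k),
    class = "cgfi_population"
  )
}

#' Population covariance implied by a factor model
#'
#' `Sigma0 = Lambda Phi Lambda' + Theta`. Errors if the result is not
#' positive-definite.
#'
#' @param model A `cgfi_population`.
#' @return The k x k implied covariance matrix.
#' @export
implied_population_cov <- function(model) {
  stopifnot(inherits(model, "cgfi_population"))
  Sigma <- model$Lambda %*% model$Phi %*% t(model$Lambda)
  diag(Sigma) <- diag(Sigma) + model$uniquenesses
  Sigma <- (Sigma + t(Sigma)) / 2
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("implied population covariance is not positive-definite",
         call. = FALSE)
  }
  dimnames(Sigma) <- list(model$indicators, model$indicators)
  Sigma
}

#' Generate multivariate-normal factor-model data
#'
#' Draws `n` cases from the zero-mean multivariate normal with the model's
#' implied covariance (via its Cholesky factor). Reproducible under `seed`.
#'
#' @param model A `cgfi_population`.
#' @param n Number of cases.
#' @param seed Optional integer seed (uses the current RNG stream when
#'   `NULL`).
#' @return A `cgfi_dataset`.
#' @export
generate_continuous <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "cgfi_population"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  Sigma <- implied_population_cov(model)
  L <- chol(Sigma)
  Z <- matrix(stats::rnorm(n * model$k), n, model$k)
  X <- Z %*% L
  colnames(X) <- model$indicators
  as_cgfi_dataset(X)
}

#' Generate ordinal factor-model data
#'
#' Draws continuous latent responses from the implied (correlation-metric)
#' covariance and discretizes each indicator at its thresholds into
#' categories `1..C`; marginal category proportions converge to the
#' normal-CDF gaps between thresholds.
#'
#' @inheritParams generate_continuous
#' @return A `cgfi_dataset` of integer-coded items.
#' @export
generate_ordinal <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "cgfi_population"))
  if (is.null(model$thresholds)) {
    stop("the population model has no thresholds", call. = FALSE)
  }
  latent <- generate_continuous(model, n, seed)
  X <- latent$raw
  for (v in model$indicators) {
    cuts <- c(-Inf, model$thresholds[[v]], Inf)
    X[, v] <- as.numeric(cut(X[, v], breaks = cuts, labels = FALSE))
  }
  as_cgfi_dataset(X)
}

#' Inject missing values completely at random
#'
#' Sets each cell to `NA` independently with probability `rate`, emulating
#' the "NA"-marked missingness the loader handles by listwise deletion.
#'
#' @param data A `cgfi_dataset`.
#' @param rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A `cgfi_dataset` with missing cells in its raw table.
#' @export
inject_missing <- function(data, rate, seed = NULL) {
  stopifnot(inherits(data, "cgfi_dataset"), rate >= 0, rate < 1)
  if (!is.null(seed)) set.seed(seed)
  X <- data$raw
  X[matrix(stats::runif(length(X)) < rate, nrow(X))] <- NA_real_
  as_cgfi_dataset(X)
}

#' Write a dataset to CSV
#'
#' Writes the raw rows (missing cells as the token) in the format
#' [load_csv()] reads back.
#'
#' @param data A `cgfi_dataset`.
#' @param path Output path.
#' @param missing_token Text for missing cells, default `"NA"`.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path, missing_token = "NA") {
  stopifnot(inherits(data, "cgfi_dataset"))
  utils::write.csv(as.data.frame(data$raw), path, row.names = FALSE,
                   na = missing_token, quote = FALSE)
  invisible(path)
}

#' One-factor population used throughout examples and tests
#'
#' Convenience constructor for the default scenario: `k` indicators loading
#' `loading` on one factor, unit implied variances; for ordinal data,
#' `n_categories` equiprobable-quantile thresholds per item.
#'
#' @param k Number of indicators.
#' @param loading Common loading.
#' @param n_categories If given, thresholds for that many categories are
#'   added (equal population proportions).
#' @return A `cgfi_population`.
#' @export
onefactor_population <- function(k = 7, loading = 0.7, n_categories = NULL) {
  inds <- paste0("x", seq_len(k))
  thr <- NULL
  if (!is.null(n_categories)) {
    q <- stats::qnorm(seq_len(n_categories - 1) / n_categories)
    thr <- stats::setNames(rep(list(q), k), inds)
  }
  population_model(
    loadings = list(F1 = stats::setNames(rep(loading, k), inds)),
    thresholds = thr
  )
}
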