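#' Construct a dataset object from a numeric table
#'
#' Internal constructor shared by [load_csv()] and the synthetic-data
#' generators. Keeps both the raw rows (possibly with missing values; the
#' unit the bootstrap resamples) and the listwise-complete rows that the
#' moment computations consume.
#'
#' @param values Numeric matrix or data.frame, cases in rows.
#' @param variable_names Optional column names (defaults to existing names).
#' @return An object of class `cgfi_dataset` with elements `raw`, `values`
#'   (complete rows only), `variable_names`, `n_rows_raw`, `n_rows_complete`.
#' @export
as_cgfi_dataset <- function(values, variable_names = colnames(values)) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (is.null(variable_names)) {
    variable_names <- paste0("V", seq_len(ncol(m)))
  }
  colnames(m) <- variable_names
  if (ncol(m) < 2L) stop("need at least 2 variables", call. = FALSE)
  complete <- stats::complete.cases(m)
  structure(
    list(raw = m, values = m[complete, , drop = FALSE],
         variable_names = variable_names,
         n_rows_raw = nrow(m), n_rows_complete = sum(complete)),
    class = "cgfi_dataset"
  )
}

#' @export
print.cgfi_dataset <- function(x, ...) {
  cat("CFA dataset:", x$n_rows_raw, "cases x", length(x$variable_names),
      "variables;", x$n_rows_complete, "complete after listwise deletion\n")
  invisible(x)
}

#' Load case-by-item data from a CSV file
#'
#' Reads comma-delimited data with a header row. Missing values are marked
#' by a text token (default `"NA"`). If `variables` is given, the table is
#' first restricted to those columns, so missingness in unmodeled columns
#' never drops a case; rows with a missing value in any retained column are
#' then removed (listwise deletion).
#'
#' @param path Path to the CSV file.
#' @param variables Optional character vector of columns to keep (e.g. the
#'   model's indicators).
#' @param missing_token Text marking a missing cell. Default `"NA"`.
#' @return A `cgfi_dataset`.
#' @export
load_csv <- function(path, variables = NULL, missing_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE, na.strings = character(0))
  if (ncol(raw) < 2L) stop("CSV must have at least 2 columns", call. = FALSE)
  if (!is.null(variables)) {
    absent <- setdiff(variables, names(raw))
    if (length(absent)) {
      stop("modeled variable(s) not in CSV: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    raw <- raw[, variables, drop = FALSE]
  }
  num <- matrix(NA_real_, nrow(raw), ncol(raw),
                dimnames = list(NULL, names(raw)))
  for (j in seq_along(raw)) {
    cell <- trimws(raw[[j]])
    is_missing <- cell == missing_token | cell == ""
    conv <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & is.na(conv))
    if (length(bad)) {
      stop("non-numeric value ", sQuote(raw[[j]][bad[1]]), " at row ",
           bad[1], ", column ", sQuote(names(raw)[j]), call. = FALSE)
    }
    conv[is_missing] <- NA_real_
    num[, j] <- conv
  }
  out <- as_cgfi_dataset(num)
  k <- ncol(num)
  if (out$n_rows_complete < k + 1L) {
    stop("insufficient data: only ", out$n_rows_complete,
         " complete rows for ", k, " variables", call. = FALSE)
  }
  out
}

#' Sample covariance matrix
#'
#' @param data A `cgfi_dataset` (complete rows are used).
#' @param divisor `"N"` (the maximum-likelihood form, default) or `"N-1"`.
#' @return A `cgfi_moments` object of kind `"covariance"`.
#' @export
sample_covariance <- function(data, divisor = c("N", "N-1")) {
  divisor <- match.arg(divisor)
  stopifnot(inherits(data, "cgfi_dataset"))
  x <- data$values
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 complete rows", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[v == 0], collapse = ", "), call. = FALSE)
  }
  S <- stats::cov(x)
  if (divisor == "N") S <- S * (n - 1) / n
  S <- (S + t(S)) / 2
  structure(
    list(matrix = S, thresholds = NULL, n_effective = n,
         kind = "covariance", smoothed = FALSE),
    class = "cgfi_moments"
  )
}

#' @export
print.cgfi_moments <- function(x, ...) {
  cat("Sample moments (", x$kind, "), k = ", ncol(x$matrix),
      ", n = ", x$n_effective, "\n", sep = "")
  invisible(x)
}

#' Thresholds of an ordinal variable
#'
#' Step one of the two-step polychoric estimator: thresholds are the
#' standard-normal quantiles of the cumulative category proportions,
#' `tau_c = qnorm(P(X <= c))` for all but the last category.
#'
#' @param column Integer-coded ordinal vector (missing values are dropped).
#' @return Strictly ascending numeric vector of length (categories - 1).
#' @export
estimate_thresholds <- function(column) {
  x <- column[!is.na(column)]
  lv <- sort(unique(x))
  if (length(lv) < 2L) {
    stop("ordinal variable has a single observed category", call. = FALSE)
  }
  counts <- tabulate(match(x, lv), nbins = length(lv))
  p <- cumsum(counts) / length(x)
  stats::qnorm(p[-length(p)])
}

# Bivariate standard-normal CDF P(X <= h, Y <= k) for correlation rho.
# Uses the single angular integral
#   Phi2(h, k, rho) = Phi(h) Phi(k)
#     + (1/2pi) * int_0^{asin(rho)} exp(-(h^2 + k^2 - 2 h k sin t)
#                                        / (2 cos^2 t)) dt,
# evaluated with adaptive quadrature; exact limits at rho in {0, +-1} and
# infinite arguments are handled directly.
pbvnorm <- function(h, k, rho) {
  if (is.infinite(h) || is.infinite(k)) {
    if (h == -Inf || k == -Inf) return(0)
    if (h == Inf) return(stats::pnorm(k))
    return(stats::pnorm(h))
  }
  if (abs(rho) >= 1) {
    if (rho >= 1) return(stats::pnorm(min(h, k)))
    return(max(0, stats::pnorm(h) - stats::pnorm(-k)))
  }
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  f <- function(t) {
    st <- sin(t); ct2 <- cos(t)^2
    exp(-(h^2 + k^2 - 2 * h * k * st) / (2 * ct2))
  }
  q <- stats::integrate(f, 0, asin(rho), rel.tol = 1e-10, abs.tol = 1e-12)
  stats::pnorm(h) * stats::pnorm(k) + q$value / (2 * pi)
}

# Bivariate standard-normal density; 0 at infinite arguments.
dbvnorm <- function(h, k, rho) {
  if (is.infinite(h) || is.infinite(k)) return(0)
  d <- 1 - rho^2
  exp(-(h^2 - 2 * rho * h * k + k^2) / (2 * d)) / (2 * pi * sqrt(d))
}

# Cell probabilities of the two-way table implied by thresholds and rho.
bvn_cell_probs <- function(tau_i, tau_j, rho) {
  a <- c(-Inf, tau_i, Inf)
  b <- c(-Inf, tau_j, Inf)
  G <- outer(seq_along(a), seq_along(b),
             Vectorize(function(i, j) pbvnorm(a[i], b[j], rho)))
  P <- G[-1, -1, drop = FALSE] - G[-nrow(G), -1, drop = FALSE] -
    G[-1, -ncol(G), drop = FALSE] + G[-nrow(G), -ncol(G), drop = FALSE]
  pmax(P, 0)
}

#' Polychoric correlation of two ordinal variables
#'
#' Step two of the two-step estimator: with thresholds fixed at their
#' univariate estimates, the latent correlation maximizes the multinomial
#' likelihood of the observed contingency table under a bivariate-normal
#' model. The estimate is bounded away from +-1 by 1e-4.
#'
#' @param col_i,col_j Integer-coded ordinal vectors (pairwise complete cases
#'   are used).
#' @param thresholds_i,thresholds_j Thresholds from [estimate_thresholds()];
#'   computed from the columns when omitted.
#' @return The estimated correlation, with attributes `converged` (logical)
#'   and `n_pairs`.
#' @export
polychoric_correlation <- function(col_i, col_j,
                                   thresholds_i = NULL, thresholds_j = NULL) {
  ok <- !is.na(col_i) & !is.na(col_j)
  x <- col_i[ok]; y <- col_j[ok]
  if (length(x) == 0L) stop("empty contingency table", call. = FALSE)
  if (is.null(thresholds_i)) thresholds_i <- estimate_thresholds(x)
  if (is.null(thresholds_j)) thresholds_j <- estimate_thresholds(y)
  lx <- sort(unique(x)); ly <- sort(unique(y))
  if (length(lx) < 2L || length(ly) < 2L) {
    stop("ordinal variable has a single observed category", call. = FALSE)
  }
  counts <- table(factor(x, levels = lx), factor(y, levels = ly))
  counts <- matrix(as.numeric(counts), nrow = length(lx))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate contingency table: empty row or column", call. = FALSE)
  }
  negll <- function(rho) {
    P <- bvn_cell_probs(thresholds_i, thresholds_j, rho)
    -sum(counts * log(pmax(P, 1e-12)))
  }
  bound <- 1 - 1e-4
  opt <- stats::optimize(negll, interval = c(-bound, bound), tol = 1e-7)
  rho <- opt$minimum
  # optimize() cannot report failure; treat an estimate pinned to the search
  # boundary as a non-converged (flagged) solution.
  converged <- abs(rho) < bound - 1e-6
  structure(rho, converged = converged, n_pairs = length(x))
}

#' Polychoric correlation matrix with thresholds
#'
#' Assembles the pairwise polychoric matrix for an ordinal dataset. Whenever
#' the pairwise-assembled matrix has an eigenvalue below 1e-8 it is smoothed
#' to the nearest unit-diagonal positive-semidefinite matrix by eigenvalue
#' clipping, and the result is flagged (`smoothed = TRUE`).
#'
#' @param data A `cgfi_dataset` of integer-coded ordinal variables.
#' @return A `cgfi_moments` object of kind `"polychoric"` with per-variable
#'   `thresholds`.
#' @export
polychoric_moments <- function(data) {
  stopifnot(inherits(data, "cgfi_dataset"))
  x <- data$values
  k <- ncol(x)
  vars <- colnames(x)
  thresholds <- lapply(seq_len(k), function(j) estimate_thresholds(x[, j]))
  names(thresholds) <- vars
  R <- diag(k)
  flagged <- FALSE
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    r <- polychoric_correlation(x[, i], x[, j],
                                thresholds[[i]], thresholds[[j]])
    if (!attr(r, "converged")) flagged <- TRUE
    R[i, j] <- R[j, i] <- as.numeric(r)
  }
  dimnames(R) <- list(vars, vars)
  smoothed <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    lam <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    d <- 1 / sqrt(diag(R))
    R <- R * tcrossprod(d)
    diag(R) <- 1
    dimnames(R) <- list(vars, vars)
    smoothed <- TRUE
  }
  structure(
    list(matrix = R, thresholds = thresholds, n_effective = nrow(x),
         kind = "polychoric", smoothed = smoothed,
         pairwise_flagged = flagged),
    class = "cgfi_moments"
  )
}

#' Compute the sample moments a model consumes
#'
#' Dispatches on the model's data kind: covariance matrix for continuous
#' models, thresholds plus polychoric correlation matrix for ordinal models.
#' The flag in the model (not anything about the data values) decides the
#' treatment.
#'
#' @param data A `cgfi_dataset`.
#' @param spec A `cgfi_model`.
#' @param divisor Covariance divisor, `"N"` or `"N-1"` (continuous only).
#' @return A `cgfi_moments` object.
#' @export
compute_moments <- function(data, spec, divisor = c("N", "N-1")) {
  stopifnot(inherits(data, "cgfi_dataset"), inherits(spec, "cgfi_model"))
  absent <- setdiff(spec$indicators, data$variable_names)
  if (length(absent)) {
    stop("dataset lacks modeled variable(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  sub <- as_cgfi_dataset(data$raw[, spec$indicators, drop = FALSE])
  if (sub$n_rows_complete < spec$k + 1L) {
    stop("insufficient data: only ", sub$n_rows_complete,
         " complete rows for ", spec$k, " variables", call. = FALSE)
  }
  if (spec$data_kind == "continuous") {
    sample_covariance(sub, divisor = match.arg(divisor))
  } else {
    polychoric_moments(sub)
  }
}
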