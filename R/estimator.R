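# Model-fitting engine: normal-theory ML/GLS on covariance matrices and
# ULS/DWLS/WLS on polychoric correlation matrices, all minimized with
# L-BFGS-B using analytic gradients.

#' Normal-theory maximum-likelihood discrepancy
#'
#' `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - k`, which is 0 iff
#' `Sigma == S` and positive otherwise.
#'
#' @param S Sample covariance matrix (positive-definite).
#' @param Sigma Model-implied covariance matrix (positive-definite).
#' @return Scalar discrepancy value (>= 0 up to round-off).
#' @export
ml_discrepancy <- function(S, Sigma) {
  k <- ncol(S)
  stopifnot(ncol(Sigma) == k, nrow(S) == k, nrow(Sigma) == k)
  cS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(cS)) stop("sample covariance matrix is singular", call. = FALSE)
  cZ <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cZ)) stop("implied covariance matrix is singular", call. = FALSE)
  Sigma_inv <- chol2inv(cZ)
  2 * sum(log(diag(cZ))) + sum(S * Sigma_inv) - 2 * sum(log(diag(cS))) - k
}

#' Least-squares discrepancy on correlation moments
#'
#' Weighted sum of squared residuals over the non-redundant correlation
#' moments (lower off-diagonal cells): `F = (s - sigma)' W^-1 (s - sigma)`.
#' ULS takes `W = I`; DWLS takes the diagonal of asymptotic variances;
#' WLS takes the full asymptotic covariance matrix of the moments.
#' Threshold moments, which the fitting routine reproduces exactly, have
#' zero residual and are omitted.
#'
#' @param R Sample (polychoric) correlation matrix.
#' @param Sigma Implied correlation matrix.
#' @param weights `"ULS"`, `"DWLS"` or `"WLS"`.
#' @param avar For DWLS: vector of asymptotic variances of the lower
#'   off-diagonal moments, in column-major lower-triangle order.
#' @param W For WLS: full asymptotic covariance matrix of those moments.
#' @return Scalar discrepancy value (>= 0).
#' @export
ls_discrepancy <- function(R, Sigma, weights = c("ULS", "DWLS", "WLS"),
                           avar = NULL, W = NULL) {
  weights <- match.arg(weights)
  r <- R[lower.tri(R)] - Sigma[lower.tri(Sigma)]
  switch(weights,
    ULS = sum(r^2),
    DWLS = {
      if (is.null(avar) || length(avar) != length(r)) {
        stop("DWLS needs one asymptotic variance per moment", call. = FALSE)
      }
      sum(r^2 / avar)
    },
    WLS = {
      if (is.null(W)) stop("WLS needs the full weight matrix", call. = FALSE)
      Wi <- tryCatch(solve(W, r), error = function(e) {
        stop("weight matrix is not invertible; consider DWLS", call. = FALSE)
      })
      drop(crossprod(r, Wi))
    }
  )
}

# ---- parameter packing ----------------------------------------------------

# Maps the free parameters of a model onto a flat numeric vector and back.
# Layout: loadings (factor-major), free factor variances, factor covariances
# (lower-triangle order), uniquenesses (continuous only).
par_map <- function(spec) {
  tmpl <- build_template(spec)
  k <- spec$k
  nf <- length(spec$factors)
  ind_row <- stats::setNames(seq_len(k), spec$indicators)
  first_fixed <- spec$identification == "first_loading_fixed"

  load_free <- NULL   # rows: (indicator row, factor col)
  load_fixed <- NULL  # rows: (indicator row, factor col, value)
  for (f in seq_len(nf)) {
    inds <- spec$loadings[[spec$factors[f]]]
    for (i in seq_along(inds)) {
      r <- ind_row[[inds[i]]]
      if (first_fixed && i == 1L) {
        load_fixed <- rbind(load_fixed, c(r, f, 1.0))
      } else {
        load_free <- rbind(load_free, c(r, f))
      }
    }
  }
  fcov <- NULL
  if (nf > 1L) {
    for (i in 1:(nf - 1L)) for (j in (i + 1L):nf) fcov <- rbind(fcov, c(j, i))
  }
  n_load <- if (is.null(load_free)) 0L else nrow(load_free)
  n_fvar <- if (first_fixed) nf else 0L
  n_fcov <- if (is.null(fcov)) 0L else nrow(fcov)
  n_uniq <- if (spec$data_kind == "continuous") k else 0L
  idx <- list(
    load = seq_len(n_load),
    fvar = n_load + seq_len(n_fvar),
    fcov = n_load + n_fvar + seq_len(n_fcov),
    uniq = n_load + n_fvar + n_fcov + seq_len(n_uniq)
  )
  n_par <- n_load + n_fvar + n_fcov + n_uniq
  list(spec = spec, template = tmpl, k = k, nf = nf,
       first_fixed = first_fixed, load_free = load_free,
       load_fixed = load_fixed, fcov = fcov, idx = idx, n_par = n_par)
}

map_start <- function(map) {
  th <- numeric(map$n_par)
  th[map$idx$load] <- 0.7
  th[map$idx$fvar] <- 0.5
  th[map$idx$fcov] <- 0.0
  th[map$idx$uniq] <- 0.3
  th
}

map_bounds <- function(map) {
  lower <- rep(-Inf, map$n_par)
  upper <- rep(Inf, map$n_par)
  lower[map$idx$fvar] <- 1e-4
  if (!map$first_fixed) {
    lower[map$idx$fcov] <- -0.999
    upper[map$idx$fcov] <- 0.999
  }
  lower[map$idx$uniq] <- 1e-4
  list(lower = lower, upper = upper)
}

# Unpack theta into Lambda (k x nf), Phi (nf x nf) and the uniqueness
# vector (continuous: free; ordinal delta: 1 - communality).
map_matrices <- function(theta, map) {
  k <- map$k; nf <- map$nf
  Lambda <- matrix(0, k, nf)
  if (!is.null(map$load_free)) {
    Lambda[map$load_free[, 1:2, drop = FALSE]] <- theta[map$idx$load]
  }
  if (!is.null(map$load_fixed)) {
    Lambda[map$load_fixed[, 1:2, drop = FALSE]] <- map$load_fixed[, 3]
  }
  Phi <- diag(nf)
  if (map$first_fixed) diag(Phi) <- theta[map$idx$fvar]
  if (!is.null(map$fcov)) {
    Phi[map$fcov] <- theta[map$idx$fcov]
    Phi[map$fcov[, 2:1, drop = FALSE]] <- theta[map$idx$fcov]
  }
  communality <- diag(Lambda %*% Phi %*% t(Lambda))
  theta_diag <- if (map$spec$data_kind == "continuous") {
    theta[map$idx$uniq]
  } else {
    pmax(1 - communality, 1e-4)
  }
  list(Lambda = Lambda, Phi = Phi, theta_diag = theta_diag,
       communality = communality)
}

# Ensure Phi is usable (PD); clip eigenvalues if an optimizer step left the
# free covariances inconsistent. Rarely triggered with <= 2 factors.
phi_safe <- function(Phi) {
  if (ncol(Phi) == 1L) return(Phi)
  ev <- eigen(Phi, symmetric = TRUE)
  if (min(ev$values) > 1e-8) return(Phi)
  ev$vectors %*% diag(pmax(ev$values, 1e-6), ncol(Phi)) %*% t(ev$vectors)
}

# ---- objective/gradient pairs ---------------------------------------------

# ML and GLS share chain rules through G with dF = tr(G dSigma):
#   ML:  G = Sigma^-1 - Sigma^-1 S Sigma^-1
#   GLS: G = A Sigma A - A, with A = S^-1 fixed
make_cov_objective <- function(map, S, estimator) {
  k <- map$k
  cS <- chol(S)
  logdetS <- 2 * sum(log(diag(cS)))
  A <- if (estimator == "GLS") chol2inv(cS) else NULL
  penalty_value <- 1e10

  fn_gr <- function(theta) {
    m <- map_matrices(theta, map)
    Phi <- phi_safe(m$Phi)
    LP <- m$Lambda %*% Phi
    Sigma <- LP %*% t(m$Lambda)
    diag(Sigma) <- diag(Sigma) + m$theta_diag
    if (estimator == "ML") {
      cZ <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(cZ)) {
        return(list(value = penalty_value + sum(theta^2), gradient = 2 * theta))
      }
      Sigma_inv <- chol2inv(cZ)
      value <- 2 * sum(log(diag(cZ))) + sum(S * Sigma_inv) - logdetS - k
      G <- Sigma_inv - Sigma_inv %*% S %*% Sigma_inv
    } else {
      value <- 0.5 * sum((diag(k) - Sigma %*% A)^2)
      G <- A %*% Sigma %*% A - A
    }
    g <- numeric(map$n_par)
    GLP <- G %*% LP
    if (length(map$idx$load)) {
      g[map$idx$load] <- 2 * GLP[map$load_free[, 1:2, drop = FALSE]]
    }
    LGL <- crossprod(m$Lambda, G %*% m$Lambda)
    if (length(map$idx$fvar)) g[map$idx$fvar] <- diag(LGL)
    if (length(map$idx$fcov)) g[map$idx$fcov] <- 2 * LGL[map$fcov]
    if (length(map$idx$uniq)) g[map$idx$uniq] <- diag(G)
    list(value = value, gradient = g)
  }
  fn_gr
}

# Least-squares objective on the implied correlation matrix (delta
# parameterization: off-diagonals from Lambda Phi Lambda', diagonal fixed 1).
# `u_fun` maps the residual vector r (lower off-diagonal) to W^-1 r.
# A smooth barrier keeps communalities below 1 (Heywood protection).
make_ls_objective <- function(map, R, u_fun) {
  k <- map$k
  lower_idx <- which(lower.tri(R))
  r_obs <- R[lower_idx]
  pen_c <- 1e4
  cap <- 1 - 1e-4

  fn_gr <- function(theta) {
    m <- map_matrices(theta, map)
    Phi <- phi_safe(m$Phi)
    LP <- m$Lambda %*% Phi
    P <- LP %*% t(m$Lambda)
    r <- r_obs - P[lower_idx]
    u <- u_fun(r)
    value <- sum(r * u)

    M <- matrix(0, k, k)
    M[lower_idx] <- u
    M <- M + t(M)
    g <- numeric(map$n_par)
    MLP <- M %*% LP
    if (length(map$idx$load)) {
      g[map$idx$load] <- -2 * MLP[map$load_free[, 1:2, drop = FALSE]]
    }
    LML <- crossprod(m$Lambda, M %*% m$Lambda)
    if (length(map$idx$fvar)) g[map$idx$fvar] <- -diag(LML)
    if (length(map$idx$fcov)) g[map$idx$fcov] <- -2 * LML[map$fcov]

    excess <- pmax(m$communality - cap, 0)
    if (any(excess > 0)) {
      value <- value + pen_c * sum(excess^2)
      w_pen <- 2 * pen_c * excess
      if (length(map$idx$load)) {
        rows <- map$load_free[, 1]
        cols <- map$load_free[, 2]
        g[map$idx$load] <- g[map$idx$load] +
          w_pen[rows] * 2 * LP[cbind(rows, cols)]
      }
      if (length(map$idx$fvar)) {
        g[map$idx$fvar] <- g[map$idx$fvar] +
          colSums(w_pen * m$Lambda^2)
      }
      if (length(map$idx$fcov)) {
        for (q in seq_len(nrow(map$fcov))) {
          f <- map$fcov[q, 1]; gg <- map$fcov[q, 2]
          g[map$idx$fcov[q]] <- g[map$idx$fcov[q]] +
            sum(w_pen * 2 * m$Lambda[, f] * m$Lambda[, gg])
        }
      }
    }
    list(value = value, gradient = g)
  }
  fn_gr
}

# ---- weights for DWLS/WLS -------------------------------------------------

# Asymptotic covariance (Gamma) of the two-step polychoric estimates via
# influence functions. Per pair (i, j), the case-level influence is
# score(cell)/information, with the score from Plackett's identity
# d pi_ab / d rho = phi2 at the four cell corners. DWLS uses diag(Gamma);
# WLS uses the empirical covariance of the influence functions across cases.
polychoric_acov <- function(data_values, moments, full = FALSE) {
  x <- data_values
  k <- ncol(x)
  n <- nrow(x)
  pairs <- which(lower.tri(diag(k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2], pairs[, 1]), , drop = FALSE]
  np <- nrow(pairs)
  psi <- matrix(0, n, np)
  for (q in seq_len(np)) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    rho <- moments$matrix[i, j]
    ti <- moments$thresholds[[i]]; tj <- moments$thresholds[[j]]
    ai <- c(-Inf, ti, Inf); aj <- c(-Inf, tj, Inf)
    P <- bvn_cell_probs(ti, tj, rho)
    nb_i <- length(ai) - 1L; nb_j <- length(aj) - 1L
    D <- matrix(0, nb_i, nb_j)
    for (a in seq_len(nb_i)) for (b in seq_len(nb_j)) {
      D[a, b] <- dbvnorm(ai[a + 1], aj[b + 1], rho) -
        dbvnorm(ai[a], aj[b + 1], rho) -
        dbvnorm(ai[a + 1], aj[b], rho) + dbvnorm(ai[a], aj[b], rho)
    }
    score <- D / pmax(P, 1e-12)
    info <- sum(pmax(P, 1e-12) * score^2)
    ci <- cut_by_thresholds(x[, i], ti)
    cj <- cut_by_thresholds(x[, j], tj)
    psi[, q] <- score[cbind(ci, cj)] / max(info, 1e-12)
  }
  if (full) {
    crossprod(psi) / n
  } else {
    colMeans(psi^2)
  }
}

# Assign ordinal values to cells 1..C using the empirical category order.
cut_by_thresholds <- function(column, thresholds) {
  lv <- sort(unique(column))
  match(column, lv)
}

pair_index_order <- function(k) {
  which(lower.tri(diag(k)))
}

# ---- main fitting routines ------------------------------------------------

run_optim <- function(fn_gr, start, bounds, maxit = 1000L) {
  fn <- function(th) fn_gr(th)$value
  gr <- function(th) fn_gr(th)$gradient
  stats::optim(start, fn = fn, gr = gr, method = "L-BFGS-B",
               lower = bounds$lower, upper = bounds$upper,
               control = list(maxit = maxit, factr = 1e7))
}

#' Fit a confirmatory factor model to sample moments
#'
#' Minimizes the estimator's discrepancy function over the model's free
#' parameters with a quasi-Newton optimizer (analytic gradients, bound
#' constraints for variances, up to `restarts` jittered restarts on
#' non-convergence). Uniquenesses are bounded below at 1e-4; a fit where
#' that bound (or, for ordinal models, the unit-communality cap) binds is
#' flagged as a Heywood case with a warning.
#'
#' @param spec A `cgfi_model`.
#' @param moments A `cgfi_moments` object of the matching kind: covariance
#'   for `ML`/`GLS`, polychoric for `ULS`/`DWLS`/`WLS`.
#' @param estimator One of `"ML"`, `"GLS"`, `"ULS"`, `"DWLS"`, `"WLS"`.
#' @param data For `DWLS`/`WLS` only: the `cgfi_dataset` the moments came
#'   from (needed to estimate the asymptotic variances of the polychoric
#'   moments).
#' @param start Optional start vector for the free parameters.
#' @param chi_multiplier `"N"` (default) or `"N-1"`: the factor converting
#'   the minimized discrepancy into the chi-square statistic.
#' @param restarts Maximum number of jittered restarts (uses the current
#'   RNG stream, so fits are reproducible under a set seed).
#' @return An object of class `cgfi_fit`.
#' @export
fit_cfa <- function(spec, moments,
                    estimator = c("ML", "GLS", "ULS", "DWLS", "WLS"),
                    data = NULL, start = NULL,
                    chi_multiplier = c("N", "N-1"), restarts = 5L) {
  estimator <- match.arg(estimator)
  chi_multiplier <- match.arg(chi_multiplier)
  stopifnot(inherits(spec, "cgfi_model"), inherits(moments, "cgfi_moments"))
  check_estimator_kind(estimator, moments$kind)
  df <- model_df(spec)
  map <- par_map(spec)
  k <- map$k
  vars <- colnames(moments$matrix)
  if (!identical(vars, spec$indicators)) {
    if (!setequal(vars, spec$indicators)) {
      stop("moments and model cover different variables", call. = FALSE)
    }
    perm <- match(spec$indicators, vars)
    moments$matrix <- moments$matrix[perm, perm]
    if (!is.null(moments$thresholds)) {
      moments$thresholds <- moments$thresholds[perm]
    }
  }

  ls_weights <- NULL
  if (estimator %in% c("ULS", "DWLS", "WLS")) {
    u_fun <- switch(estimator,
      ULS = function(r) r,
      DWLS = {
        if (is.null(data)) {
          stop("DWLS needs `data` to estimate moment asymptotic variances",
               call. = FALSE)
        }
        avar <- polychoric_acov(
          as_cgfi_dataset(data$raw[, spec$indicators, drop = FALSE])$values,
          moments, full = FALSE)
        ls_weights <- list(avar = pmax(avar, 1e-10))
        function(r) r / ls_weights$avar
      },
      WLS = {
        if (is.null(data)) {
          stop("WLS needs `data` to estimate the full weight matrix",
               call. = FALSE)
        }
        if (k > 25L) {
          stop("WLS full weight matrix limited to k <= 25; use DWLS",
               call. = FALSE)
        }
        W <- polychoric_acov(
          as_cgfi_dataset(data$raw[, spec$indicators, drop = FALSE])$values,
          moments, full = TRUE)
        Wi <- tryCatch(solve(W), error = function(e) {
          stop("weight matrix is not invertible; consider DWLS",
               call. = FALSE)
        })
        ls_weights <- list(W = W)
        function(r) drop(Wi %*% r)
      })
    fn_gr <- make_ls_objective(map, moments$matrix, u_fun)
  } else {
    fn_gr <- make_cov_objective(map, moments$matrix, estimator)
  }

  bounds <- map_bounds(map)
  start0 <- if (is.null(start)) map_start(map) else start
  best <- NULL
  converged <- FALSE
  attempts <- 0L
  th_try <- start0
  repeat {
    res <- tryCatch(run_optim(fn_gr, th_try, bounds),
                    error = function(e) NULL)
    attempts <- attempts + 1L
    if (!is.null(res)) {
      if (is.null(best) || res$value < best$value) best <- res
      if (res$convergence == 0 && res$value < 1e9) {
        converged <- TRUE
        best <- if (res$value <= best$value) res else best
        break
      }
    }
    if (attempts > restarts) break
    th_try <- start0
    th_try[map$idx$load] <- 0.7 + stats::runif(length(map$idx$load), -0.4, 0.4)
    th_try[map$idx$fvar] <- stats::runif(length(map$idx$fvar), 0.2, 1.2)
    th_try[map$idx$fcov] <- stats::runif(length(map$idx$fcov), -0.4, 0.4)
    th_try[map$idx$uniq] <- stats::runif(length(map$idx$uniq), 0.1, 0.8)
  }
  if (is.null(best)) stop("optimization failed to produce any fit",
                          call. = FALSE)

  theta_hat <- best$par
  m <- map_matrices(theta_hat, map)
  implied <- m$Lambda %*% m$Phi %*% t(m$Lambda)
  diag_implied <- diag(implied) + m$theta_diag
  if (spec$data_kind == "ordinal") diag_implied <- rep(1, k)
  diag(implied) <- diag_implied
  dimnames(implied) <- dimnames(moments$matrix)

  # F at the optimum, without the Heywood barrier term
  F_min <- if (estimator %in% c("ML", "GLS")) {
    if (estimator == "ML") ml_discrepancy(moments$matrix, implied)
    else 0.5 * sum((diag(k) - implied %*% solve(moments$matrix))^2)
  } else {
    ls_discrepancy(moments$matrix, implied, weights = estimator,
                   avar = ls_weights$avar, W = ls_weights$W)
  }
  F_min <- max(F_min, 0)

  heywood <- FALSE
  if (spec$data_kind == "continuous") {
    if (any(theta_hat[map$idx$uniq] <= 1e-4 + 1e-8)) heywood <- TRUE
  } else if (any(m$communality >= 1 - 1e-4 - 1e-8)) {
    heywood <- TRUE
  }
  if (heywood) {
    warning("Heywood case: a uniqueness estimate hit its lower bound",
            call. = FALSE)
  }

  n <- moments$n_effective
  mult <- if (chi_multiplier == "N") n else n - 1
  if (df == 0L) {
    chi_square <- 0
    p_value <- 1
  } else {
    chi_square <- mult * F_min
    p_value <- stats::pchisq(chi_square, df, lower.tail = FALSE)
  }

  loglik <- NULL
  if (estimator == "ML") {
    Sigma_inv <- chol2inv(chol(implied))
    loglik <- -n / 2 * (k * log(2 * pi) +
                          2 * sum(log(diag(chol(implied)))) +
                          sum(moments$matrix * Sigma_inv))
  }

  tmpl <- map$template
  tmpl$entries$value <- fill_template_values(map, theta_hat, m, moments)

  structure(
    list(spec = spec, template = tmpl, Lambda = m$Lambda, Phi = m$Phi,
         theta_diag = m$theta_diag, implied = implied, F_min = F_min,
         chi_square = chi_square, df = df, p_value = p_value,
         estimator = estimator, converged = converged, heywood = heywood,
         n_effective = n, chi_multiplier = chi_multiplier, loglik = loglik,
         ls_weights = ls_weights, moments_kind = moments$kind,
         attempts = attempts),
    class = "cgfi_fit"
  )
}

fill_template_values <- function(map, theta, m, moments) {
  e <- map$template$entries
  vals <- e$value
  spec <- map$spec
  free_load <- which(e$role == "loading" & e$status == "free")
  vals[free_load] <- theta[map$idx$load]
  if (map$first_fixed) {
    vals[e$role == "factor_variance"] <- theta[map$idx$fvar]
  }
  if (length(map$idx$fcov)) {
    vals[e$role == "factor_covariance"] <- theta[map$idx$fcov]
  }
  if (spec$data_kind == "continuous") {
    vals[e$role == "uniqueness"] <- theta[map$idx$uniq]
  } else {
    vals[e$role == "uniqueness" & e$status == "fixed"] <- m$theta_diag
    th_rows <- which(e$role == "threshold")
    vals[th_rows] <- unlist(moments$thresholds[spec$indicators],
                            use.names = FALSE)
  }
  vals
}

check_estimator_kind <- function(estimator, kind) {
  needs_cov <- estimator %in% c("ML", "GLS")
  if (needs_cov && kind != "covariance") {
    stop(estimator, " requires covariance moments (continuous data); ",
         "use ULS/DWLS/WLS for polychoric moments", call. = FALSE)
  }
  if (!needs_cov && kind != "polychoric") {
    stop(estimator, " requires polychoric moments (ordinal data); ",
         "use ML or GLS for covariance moments", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cgfi_fit <- function(x, ...) {
  cat("CFA fit (", x$estimator, "), k = ", x$spec$k, ", n = ",
      x$n_effective, "\n", sep = "")
  cat(sprintf("  chi-square = %.3f on %d df (p = %.4g); converged: %s\n",
              x$chi_square, x$df, x$p_value, x$converged))
  invisible(x)
}

#' Fit the independence (baseline) model
#'
#' The baseline model for incremental indices (CFI, TLI) constrains all
#' covariances/correlations to zero. For ML its minimum has the closed form
#' `F_B = sum(log s_ii) - log|S|`; for GLS the optimal diagonal solves a
#' linear system; for correlation-metric estimators the implied matrix is
#' the identity and the (weighted) sum of squared sample correlations is the
#' discrepancy. Baseline df is `k(k-1)/2` in all metrics.
#'
#' @inheritParams fit_cfa
#' @param target Optional `cgfi_fit` of the target model; reuses its
#'   DWLS/WLS weights so both models are scored against the same metric.
#' @return A `cgfi_fit` (with `baseline = TRUE`).
#' @export
fit_baseline <- function(spec, moments,
                         estimator = c("ML", "GLS", "ULS", "DWLS", "WLS"),
                         data = NULL, chi_multiplier = c("N", "N-1"),
                         target = NULL) {
  estimator <- match.arg(estimator)
  chi_multiplier <- match.arg(chi_multiplier)
  check_estimator_kind(estimator, moments$kind)
  S <- moments$matrix
  k <- ncol(S)
  n <- moments$n_effective
  df_B <- k * (k - 1L) / 2L

  if (estimator == "ML") {
    implied <- diag(diag(S), k)
    F_B <- sum(log(diag(S))) - 2 * sum(log(diag(chol(S))))
  } else if (estimator == "GLS") {
    A <- chol2inv(chol(S))
    d <- solve(A * A, diag(A))
    implied <- diag(drop(d), k)
    F_B <- 0.5 * sum((diag(k) - implied %*% A)^2)
  } else {
    implied <- diag(k)
    lw <- if (!is.null(target)) target$ls_weights else NULL
    if (estimator != "ULS" && is.null(lw)) {
      if (is.null(data)) {
        stop("baseline for ", estimator,
             " needs `data` or a fitted `target` for the weights",
             call. = FALSE)
      }
      vals <- as_cgfi_dataset(data$raw[, spec$indicators, drop = FALSE])$values
      lw <- if (estimator == "DWLS") {
        list(avar = pmax(polychoric_acov(vals, moments, FALSE), 1e-10))
      } else {
        list(W = polychoric_acov(vals, moments, TRUE))
      }
    }
    F_B <- ls_discrepancy(S, implied, weights = estimator,
                          avar = lw$avar, W = lw$W)
  }
  dimnames(implied) <- dimnames(S)
  F_B <- max(F_B, 0)
  mult <- if (chi_multiplier == "N") n else n - 1
  chi_B <- mult * F_B
  structure(
    list(spec = spec, implied = implied, F_min = F_B, chi_square = chi_B,
         df = df_B, p_value = stats::pchisq(chi_B, df_B, lower.tail = FALSE),
         estimator = estimator, converged = TRUE, heywood = FALSE,
         n_effective = n, chi_multiplier = chi_multiplier, loglik = NULL,
         moments_kind = moments$kind, baseline = TRUE),
    class = "cgfi_fit"
  )
}
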