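# Shared fixtures and independent oracles for the test suite.

spec_k7 <- function() {
  parse_model(paste("F1 =~", paste(paste0("x", 1:7), collapse = " + ")))
}

pop_k7 <- function(loading = 0.7) onefactor_population(7, loading)

moments_from_matrix <- function(S, n, kind = "covariance") {
  structure(list(matrix = S, thresholds = NULL, n_effective = n,
                 kind = kind, smoothed = FALSE),
            class = "cgfi_moments")
}

# Independent median-unbiased (Hyndman-Fan type 8) quantile, written from
# the plotting-position formula rather than stats::quantile().
oracle_quantile8 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n + 1 / 3) * p + 1 / 3
  h <- min(max(h, 1), n)
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Independent brute-force CFA oracle: implied covariance assembled with
# explicit loops, ML discrepancy written out from its formula, minimized by
# Nelder-Mead refined with BFGS (numerical derivatives). Unit factor
# variances; `pattern` is a list of integer indicator indices per factor.
oracle_fit_ml <- function(S, n, pattern) {
  k <- ncol(S)
  nf <- length(pattern)
  n_load <- length(unlist(pattern))
  n_cor <- nf * (nf - 1) / 2
  objective <- function(par) {
    lam <- par[seq_len(n_load)]
    psi <- par[n_load + seq_len(k)]
    if (any(psi <= 0)) return(1e8)
    rho <- if (n_cor > 0) par[n_load + k + seq_len(n_cor)] else numeric(0)
    if (any(abs(rho) >= 1)) return(1e8)
    L <- matrix(0, k, nf)
    pos <- 1L
    for (f in seq_len(nf)) {
      for (i in pattern[[f]]) {
        L[i, f] <- lam[pos]
        pos <- pos + 1L
      }
    }
    Phi <- diag(nf)
    pos <- 1L
    if (nf > 1) {
      for (a in 1:(nf - 1)) for (b in (a + 1):nf) {
        Phi[a, b] <- Phi[b, a] <- rho[pos]
        pos <- pos + 1L
      }
    }
    Sig <- matrix(0, k, k)
    for (i in 1:k) for (j in 1:k) {
      acc <- 0
      for (a in 1:nf) for (b in 1:nf) {
        acc <- acc + L[i, a] * Phi[a, b] * L[j, b]
      }
      Sig[i, j] <- acc
    }
    diag(Sig) <- diag(Sig) + psi
    dt <- det(Sig)
    if (dt <= 0) return(1e8)
    log(dt) + sum(diag(S %*% solve(Sig))) - log(det(S)) - k
  }
  start <- c(rep(0.5, n_load), rep(0.5, k), rep(0, n_cor))
  o1 <- stats::optim(start, objective, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-12))
  o2 <- stats::optim(o1$par, objective, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14))
  best <- if (o2$value < o1$value) o2 else o1
  list(F_min = best$value, chi_square = n * best$value,
       loadings = abs(best$par[seq_len(n_load)]))
}

# Numeric double-integral bivariate normal CDF (independent of pbvnorm's
# angular form): P(X <= h, Y <= k) via the conditional decomposition.
oracle_pbvnorm <- function(h, k, rho) {
  f <- function(x) {
    stats::dnorm(x) * stats::pnorm((k - rho * x) / sqrt(1 - rho^2))
  }
  stats::integrate(f, -Inf, h, rel.tol = 1e-10)$value
}
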