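test_that("GFI forms match hand arithmetic and are permutation-invariant", {
  S <- implied_population_cov(pop_k7())
  expect_equal(compute_gfi(S, S, "ML"), 1)

  Sig <- diag(2)
  Sig[1, 2] <- Sig[2, 1] <- 0.1
  expect_equal(compute_gfi(diag(2), Sig, "ULS"), 1 - 0.02 / 2)

  set.seed(6)
  A <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  B <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  p <- sample(5)
  expect_equal(compute_gfi(A[p, p], B[p, p], "ML"), compute_gfi(A, B, "ML"))
})

test_that("AGFI penalizes by df", {
  expect_equal(compute_agfi(1, 7, 14), 1)
  expect_equal(compute_agfi(0.9, 4, 2), 0.5)
  expect_true(is.na(compute_agfi(0.97, 3, 0)))
  # penalty direction: AGFI <= GFI when GFI <= 1
  expect_lte(compute_agfi(0.93, 7, 14), 0.93)
})

test_that("the CGFI correction reproduces both worked examples", {
  expect_equal(round(compute_cgfi(0.945, 7, 14, 193), 3), 0.950)
  expect_equal(compute_cgfi(0.945, 7, 14, 193), 0.945 + 1 / 193)
  expect_equal(round(compute_cgfi(0.997, 14, 77, 4540), 3), 0.997)
  # correction vanishes with n
  expect_equal(compute_cgfi(0.9, 7, 14, 1e9), 0.9, tolerance = 1e-8)
  # correction positive whenever df below the saturated bound
  expect_gt(compute_cgfi(0.9, 7, 14, 50), 0.9)
  # cap with warning
  expect_warning(v <- compute_cgfi(0.9999, 7, 14, 20), "capped")
  expect_equal(as.numeric(v), 1)
})

test_that("CFI and TLI follow the noncentrality formulas", {
  r <- compute_cfi_tli(30, 14, 500, 21)
  expect_equal(r$cfi, 1 - 16 / 479)
  expect_equal(r$tli, (500 / 21 - 30 / 14) / (500 / 21 - 1))
  expect_equal(compute_cfi_tli(14, 14, 400, 21)$cfi, 1)
  expect_equal(compute_cfi_tli(100, 21, 100, 21)$cfi, 0)
  # baseline fits: CFI 1, TLI undefined
  r0 <- compute_cfi_tli(10, 5, 20, 21)
  expect_equal(r0$cfi, 1)
  expect_true(is.na(r0$tli))
})

test_that("RMSEA and SRMR match hand arithmetic", {
  expect_equal(compute_rmsea(10, 14, 200), 0)
  expect_equal(compute_rmsea(28, 14, 192), sqrt(14 / 2688))
  expect_gt(compute_rmsea(28, 14, 100), compute_rmsea(28, 14, 200))
  expect_true(is.na(compute_rmsea(5, 0, 100)))

  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  Sig <- matrix(c(1, 0.44, 0.44, 1), 2)
  expect_equal(compute_srmr(S, Sig), sqrt(0.0036 / 3))
  expect_equal(compute_srmr(S, S), 0)
  # invariant to joint rescaling of a variable
  D <- diag(c(3, 0.5))
  expect_equal(compute_srmr(D %*% S %*% D, D %*% Sig %*% D),
               compute_srmr(S, Sig))
})

test_that("information criteria exist only under ML", {
  r <- compute_aic_bic(0, 3, exp(2))
  expect_equal(r$aic, 6)
  expect_equal(r$bic, 6)
  r2 <- compute_aic_bic(-100, 5, 150)
  expect_equal(r2$bic - r2$aic, 5 * (log(150) - 2))
  r3 <- compute_aic_bic(NULL, 5, 150)
  expect_true(is.na(r3$aic) && is.na(r3$bic))
})

test_that("CGFI equals the free-parameter form on every fitted model", {
  fits <- list()
  d <- generate_continuous(pop_k7(), 250, seed = 61)
  mom <- compute_moments(d, spec_k7())
  set.seed(10)
  fits[[1]] <- list(fit_cfa(spec_k7(), mom), fit_baseline(spec_k7(), mom),
                    mom)
  pop5 <- onefactor_population(5, 0.7, n_categories = 4)
  spec5 <- parse_model("F =~ x1 + x2 + x3 + x4 + x5",
                       data_kind = "ordinal", n_categories = 4)
  d5 <- generate_ordinal(pop5, 600, seed = 62)
  mom5 <- compute_moments(d5, spec5)
  set.seed(11)
  f5 <- fit_cfa(spec5, mom5, estimator = "ULS")
  fits[[2]] <- list(f5, fit_baseline(spec5, mom5, estimator = "ULS"), mom5)
  for (trio in fits) {
    ix <- suppressWarnings(fit_index_set(trio[[1]], trio[[2]], trio[[3]]))
    k <- ix$k
    # parameter-count form of the correction, with the covariance-metric
    # count implied by df (identical to p_free for continuous models)
    p_cov <- k * (k + 1) / 2 - ix$df
    if (trio[[3]]$kind == "covariance") expect_equal(p_cov, ix$p_free)
    expect_equal(ix$cgfi,
                 min(1, ix$gfi + 4 * p_cov / (k * (k + 1) * ix$n)),
                 tolerance = 1e-12)
    expect_identical(ix$df + ix$p_free,
                     if (trio[[3]]$kind == "covariance") {
                       as.integer(k * (k + 1) / 2)
                     } else {
                       as.integer(k * (k - 1) / 2 + 15)
                     })
  }
})

test_that("perfect fit yields the saturated identity across indices", {
  S <- implied_population_cov(pop_k7())
  mom <- moments_from_matrix(S, 200)
  set.seed(12)
  f <- fit_cfa(spec_k7(), mom)
  b <- fit_baseline(spec_k7(), mom)
  ix <- suppressWarnings(fit_index_set(f, b, mom))
  expect_lt(ix$chi_square, 1e-6)
  expect_equal(ix$gfi, 1, tolerance = 1e-9)
  expect_equal(ix$srmr, 0, tolerance = 1e-6)
  expect_equal(ix$rmsea, 0)
  expect_equal(ix$cfi, 1)
})
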