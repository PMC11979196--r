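test_that("ML discrepancy matches hand arithmetic and its invariances", {
  S <- diag(2)
  expect_equal(ml_discrepancy(S, S), 0)
  expect_equal(ml_discrepancy(S, diag(c(2, 2))), 2 * log(2) - 1)

  set.seed(5)
  A <- crossprod(matrix(rnorm(25), 5))
  B <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  p <- sample(5)
  expect_equal(ml_discrepancy(A[p, p], B[p, p]), ml_discrepancy(A, B))
  expect_gt(ml_discrepancy(A, B), 0)
})

test_that("least-squares discrepancies follow their definitions", {
  R <- diag(3)
  expect_equal(ls_discrepancy(R, R, "ULS"), 0)

  Sig <- R
  Sig[2, 1] <- Sig[1, 2] <- -0.1
  Sig[3, 1] <- Sig[1, 3] <- 0.1
  expect_equal(ls_discrepancy(R, Sig, "ULS"), 0.02)

  avar <- c(0.5, 2, 1)
  W <- diag(avar)
  expect_equal(ls_discrepancy(R, Sig, "DWLS", avar = avar),
               ls_discrepancy(R, Sig, "WLS", W = W))
  expect_error(ls_discrepancy(R, Sig, "WLS", W = matrix(0, 3, 3)),
               "DWLS")
})

test_that("a zero-discrepancy model is recovered exactly", {
  S <- implied_population_cov(pop_k7())
  mom <- moments_from_matrix(S, 200)
  set.seed(1)
  f <- fit_cfa(spec_k7(), mom)
  expect_true(f$converged)
  expect_lt(f$F_min, 1e-9)
  expect_lt(f$chi_square, 1e-6)
  expect_equal(unname(f$Lambda[, 1]), rep(0.7, 7), tolerance = 1e-4)
  expect_equal(f$df, 14)
})

test_that("identification conventions are fit-equivalent", {
  d <- generate_continuous(pop_k7(), 300, seed = 21)
  spec_a <- spec_k7()
  spec_b <- parse_model(deparse_model(spec_a),
                        identification = "first_loading_fixed")
  mom <- compute_moments(d, spec_a)
  set.seed(2); fa <- fit_cfa(spec_a, mom)
  set.seed(2); fb <- fit_cfa(spec_b, mom)
  expect_equal(fa$F_min, fb$F_min, tolerance = 1e-8)
  expect_equal(fa$df, fb$df)
})

test_that("the minimized discrepancy is invariant to variable order", {
  d <- generate_continuous(pop_k7(), 250, seed = 22)
  mom <- compute_moments(d, spec_k7())
  set.seed(3); f1 <- fit_cfa(spec_k7(), mom)
  perm_spec <- parse_model(paste(
    "F1 =~", paste(paste0("x", c(4, 1, 7, 2, 6, 3, 5)), collapse = " + ")))
  mom_p <- compute_moments(d, perm_spec)
  set.seed(3); f2 <- fit_cfa(perm_spec, mom_p)
  expect_equal(f1$F_min, f2$F_min, tolerance = 1e-7)
})

test_that("parameters are recovered from large continuous samples", {
  d <- generate_continuous(pop_k7(), 100000, seed = 11)
  mom <- compute_moments(d, spec_k7())
  set.seed(4)
  f <- fit_cfa(spec_k7(), mom)
  expect_true(f$converged)
  expect_lt(max(abs(f$Lambda[, 1] - 0.7)), 0.01)
})

test_that("two-factor models with a factor correlation are recovered", {
  inds <- paste0("y", 1:6)
  pop <- population_model(
    loadings = list(A = stats::setNames(c(0.8, 0.7, 0.6), inds[1:3]),
                    B = stats::setNames(c(0.7, 0.6, 0.8), inds[4:6])),
    factor_correlations = matrix(c(1, 0.4, 0.4, 1), 2)
  )
  d <- generate_continuous(pop, 50000, seed = 15)
  spec <- parse_model("A =~ y1 + y2 + y3\nB =~ y4 + y5 + y6")
  set.seed(5)
  f <- fit_cfa(spec, compute_moments(d, spec))
  expect_true(f$converged)
  expect_equal(f$Phi[1, 2], 0.4, tolerance = 0.02)
  expect_lt(max(abs(f$Lambda[f$Lambda != 0] - c(0.8, 0.7, 0.6, 0.7, 0.6, 0.8))),
            0.02)
})

test_that("baseline model has closed-form chi-square and df", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  mom <- moments_from_matrix(S, 101)
  spec <- parse_model("F =~ a + b")
  b <- fit_baseline(spec, mom)
  expect_equal(b$chi_square, -101 * log(0.75), tolerance = 1e-10)
  expect_equal(b$df, 1)

  b7 <- fit_baseline(spec_k7(), moments_from_matrix(
    implied_population_cov(pop_k7()), 200))
  expect_equal(b7$df, 21)

  # diagonal S saturates the baseline
  dS <- diag(c(1, 2), 2)
  dimnames(dS) <- list(c("a", "b"), c("a", "b"))
  expect_equal(fit_baseline(spec, moments_from_matrix(dS, 50))$chi_square, 0)
})

test_that("GLS fits and agrees with ML near the truth", {
  d <- generate_continuous(pop_k7(), 2000, seed = 23)
  mom <- compute_moments(d, spec_k7())
  set.seed(6); fg <- fit_cfa(spec_k7(), mom, estimator = "GLS")
  set.seed(6); fm <- fit_cfa(spec_k7(), mom, estimator = "ML")
  expect_true(fg$converged)
  expect_equal(fg$chi_square, fm$chi_square, tolerance = 0.15)
  expect_equal(unname(fg$Lambda[, 1]), unname(fm$Lambda[, 1]),
               tolerance = 0.02)
  # GLS discrepancy is zero at exact moments
  S <- implied_population_cov(pop_k7())
  set.seed(7)
  f0 <- fit_cfa(spec_k7(), moments_from_matrix(S, 200), estimator = "GLS")
  expect_lt(f0$F_min, 1e-9)
})

test_that("ordinal DWLS/ULS/WLS fits recover the structure", {
  pop <- onefactor_population(5, 0.7, n_categories = 4)
  spec <- parse_model("F =~ x1 + x2 + x3 + x4 + x5",
                      data_kind = "ordinal", n_categories = 4)
  d <- generate_ordinal(pop, 1500, seed = 41)
  mom <- compute_moments(d, spec)
  for (est in c("ULS", "DWLS", "WLS")) {
    set.seed(8)
    f <- fit_cfa(spec, mom, estimator = est, data = d)
    expect_true(f$converged)
    expect_lt(max(abs(f$Lambda[, 1] - 0.7)), 0.05)
    expect_equal(unname(diag(f$implied)), rep(1, 5))
    expect_equal(f$df, model_df(spec))
  }
  bo <- fit_baseline(spec, mom, estimator = "ULS")
  expect_equal(bo$df, 10)
  expect_equal(bo$chi_square,
               mom$n_effective * sum(mom$matrix[lower.tri(mom$matrix)]^2))
})

test_that("estimator and moments kind must match", {
  S <- implied_population_cov(pop_k7())
  mom <- moments_from_matrix(S, 100)
  expect_error(fit_cfa(spec_k7(), mom, estimator = "DWLS"), "polychoric")
  pmom <- moments_from_matrix(diag(7), 100, kind = "polychoric")
  expect_error(fit_cfa(spec_k7(), pmom, estimator = "ML"), "covariance")
})

test_that("a saturated model reports zero chi-square and p = 1", {
  spec <- parse_model("F =~ x1 + x2 + x3")
  pop <- onefactor_population(3, 0.7)
  d <- generate_continuous(pop, 150, seed = 51)
  set.seed(9)
  f <- fit_cfa(spec, compute_moments(d, spec))
  expect_equal(f$df, 0)
  expect_equal(f$chi_square, 0)
  expect_equal(f$p_value, 1)
})
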