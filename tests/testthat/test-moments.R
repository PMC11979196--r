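write_csv_fixture <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  path
}

test_that("CSV loading applies listwise deletion after column subsetting", {
  df <- data.frame(a = 1:5, b = c(2, 4, 1, 3, 5), c = c(1, 1, 2, 2, 1))
  d <- load_csv(write_csv_fixture(df))
  expect_equal(d$n_rows_raw, 5)
  expect_equal(d$n_rows_complete, 5)
  expect_equal(colnames(d$values), c("a", "b", "c"))

  df_na <- df
  df_na$b[2] <- NA
  d2 <- load_csv(write_csv_fixture(df_na))
  expect_equal(d2$n_rows_complete, 4)

  # missingness in an unmodeled column drops nothing
  d3 <- load_csv(write_csv_fixture(df_na), variables = c("a", "c"))
  expect_equal(d3$n_rows_complete, 5)
  expect_equal(colnames(d3$values), c("a", "c"))
})

test_that("CSV loading reports bad cells and insufficient data", {
  df <- data.frame(a = c("1", "2", "oops", "4", "5"), b = 1:5)
  expect_error(load_csv(write_csv_fixture(df)), "row 3.*column.*a")

  few <- data.frame(a = c(1, 2, NA), b = c(2, 1, 3), c = c(3, 1, 2))
  expect_error(load_csv(write_csv_fixture(few)), "insufficient")

  # a custom missing token is honored
  df_tok <- data.frame(a = c("1", "-999", "3", "4", "5"), b = c(5:1))
  d <- load_csv(write_csv_fixture(df_tok), missing_token = "-999")
  expect_equal(d$n_rows_complete, 4)
})

test_that("sample covariance matches hand arithmetic", {
  d <- as_cgfi_dataset(cbind(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0)))
  m <- sample_covariance(d, divisor = "N")
  expect_equal(m$matrix, matrix(c(0.25, 0, 0, 0.25), 2,
                                dimnames = list(c("x", "y"), c("x", "y"))))
  m1 <- sample_covariance(d, divisor = "N-1")
  expect_equal(diag(m1$matrix), c(x = 1, y = 1) / 3)

  # duplicated column: off-diagonal equals the shared variance
  dd <- as_cgfi_dataset(cbind(x = c(1, 2, 4, 7), y = c(1, 2, 4, 7)))
  mm <- sample_covariance(dd)
  expect_equal(mm$matrix[1, 2], mm$matrix[1, 1])
  expect_equal(stats::cov2cor(mm$matrix)[1, 2], 1)

  const <- as_cgfi_dataset(cbind(x = rep(3, 5), y = 1:5))
  expect_error(sample_covariance(const), "zero-variance.*x")
})

test_that("thresholds are normal quantiles of cumulative proportions", {
  expect_equal(estimate_thresholds(c(rep(1, 50), rep(2, 50))), 0)
  expect_equal(estimate_thresholds(c(rep(1, 8413), rep(2, 1587))),
               stats::qnorm(0.8413))
  expect_equal(estimate_thresholds(rep(1:4, each = 25)),
               c(stats::qnorm(0.25), 0, stats::qnorm(0.75)))
  expect_error(estimate_thresholds(rep(2, 10)), "single observed category")
})

test_that("bivariate normal CDF matches an independent numeric oracle", {
  cases <- expand.grid(h = c(-1.2, 0, 0.8), k = c(-0.5, 1.5),
                       rho = c(-0.85, -0.3, 0.5, 0.95))
  for (i in seq_len(nrow(cases))) {
    expect_equal(
      cgfiboot:::pbvnorm(cases$h[i], cases$k[i], cases$rho[i]),
      oracle_pbvnorm(cases$h[i], cases$k[i], cases$rho[i]),
      tolerance = 1e-8
    )
  }
})

test_that("polychoric correlation solves the orthant identity", {
  # P(both low) = 1/4 + asin(rho)/(2*pi) = 1/3  =>  rho = 0.5
  x <- c(rep(1, 4), rep(1, 2), rep(2, 2), rep(2, 4))
  y <- c(rep(1, 4), rep(2, 2), rep(1, 2), rep(2, 4))
  rho <- polychoric_correlation(x, y, 0, 0)
  expect_equal(as.numeric(rho), 0.5, tolerance = 1e-4)

  # independent margins give rho ~ 0
  xi <- rep(c(1, 1, 2, 2), 25)
  yi <- rep(c(1, 2, 1, 2), 25)
  expect_equal(as.numeric(polychoric_correlation(xi, yi)), 0,
               tolerance = 1e-3)
})

test_that("polychoric recovery from simulated ordinal data", {
  pop <- onefactor_population(2, sqrt(0.7), n_categories = 4)
  # two indicators loading sqrt(0.7) imply latent correlation 0.7
  d <- generate_ordinal(pop, 2000, seed = 31)
  r <- polychoric_correlation(d$values[, 1], d$values[, 2])
  expect_equal(as.numeric(r), 0.7, tolerance = 0.03)
})

test_that("the polychoric matrix is symmetric with unit diagonal", {
  pop <- onefactor_population(4, 0.7, n_categories = 3)
  d <- generate_ordinal(pop, 400, seed = 12)
  m <- polychoric_moments(d)
  expect_equal(m$matrix, t(m$matrix), tolerance = 1e-10)
  expect_equal(diag(m$matrix), stats::setNames(rep(1, 4), paste0("x", 1:4)))
  expect_true(all(eigen(m$matrix, only.values = TRUE)$values > 0))
  expect_length(m$thresholds, 4)
  expect_true(all(vapply(m$thresholds, function(t) all(diff(t) > 0),
                         logical(1))))
})

test_that("the model flag, not the data, decides the moments kind", {
  pop <- onefactor_population(4, 0.7, n_categories = 3)
  d <- generate_ordinal(pop, 300, seed = 13)
  cont <- parse_model("F =~ x1 + x2 + x3 + x4")
  ordn <- parse_model("F =~ x1 + x2 + x3 + x4",
                      data_kind = "ordinal", n_categories = 3)
  expect_equal(compute_moments(d, cont)$kind, "covariance")
  expect_equal(compute_moments(d, ordn)$kind, "polychoric")
})
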