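test_that("chi-square is zero at exact fit and uses the right weights", {
  # one-level CFA on data equal to the implied matrix: chi2 = 0 at any N
  S <- implied_covariance(level_params(matrix(c(1, .8, .9), 3, 1), 0.5,
                                       c(.4, .5, .6)))
  dimnames(S) <- list(c("a", "b", "c"), c("a", "b", "c"))
  m <- build_model("cfa", factor_pattern(list(f = c("a", "b", "c"))))
  for (N in c(50, 5000)) {
    fit <- fit_model(m, list(S = S, N = N), se = FALSE)
    expect_equal(chi_square(fit)$chi2, 0, tolerance = 1e-7)
  }
  # saturated two-level model: exact fit, df 0, p-value undefined
  dec <- compute_decomposition(random_dataset(61, p = 3, G = 8))
  sat <- fit_model(build_model("saturated", indicators = dec$labels),
                   dec, se = FALSE)
  cs <- chi_square(sat)
  expect_equal(cs$chi2, 0, tolerance = 1e-7)
  expect_equal(cs$df, 0)
  expect_true(is.na(cs$p_value))
})

test_that("RMSEA follows its formula, including the printed cases", {
  expect_equal(round(rmsea(12699.87, 27, 10000), 3), 0.217)
  expect_equal(rmsea(26.089, 27, 10000), 0)      # chi2 <= df
  N <- 401; df <- 6
  expect_equal(rmsea(df + df * (N - 1), df, N), 1)
  expect_true(is.na(rmsea(5, 0, 100)))
  # monotone non-decreasing in chi2
  r <- sapply(seq(0, 100, 10), rmsea, df = 9, N = 200)
  expect_true(all(diff(r) >= 0))
})

test_that("CFI follows its formula and clamps", {
  expect_equal(cfi(5, 9, 800, 36), 1)            # chi2 <= df
  expect_equal(cfi(109, 9, 1045, 45), 0.9)       # excess 100 vs 1000
  # a model worse than its baseline clamps to 0 (the denominator keeps
  # the target excess, so it can never be zero while the numerator is
  # positive)
  expect_equal(cfi(50, 9, 8, 36), 0)
  expect_equal(cfi(5, 9, 8, 36), 1)
  # monotone non-increasing in chi2
  cc <- sapply(seq(9, 509, 50), cfi, df = 9, chi2_baseline = 1000,
               df_baseline = 36)
  expect_true(all(diff(cc) <= 0))
})

test_that("SRMR standardizes residuals by sample variances", {
  S <- matrix(c(1, .5, .5, 1), 2)
  Sig <- matrix(c(1, .4, .4, 1), 2)
  expect_equal(srmr(S, Sig), sqrt(0.01 / 3))
  expect_equal(srmr(S, S), 0)
  # permutation invariance
  set.seed(2)
  A <- crossprod(matrix(rnorm(16), 4)); B <- crossprod(matrix(rnorm(16), 4))
  perm <- c(3, 1, 4, 2)
  expect_equal(srmr(A, B), srmr(A[perm, perm], B[perm, perm]))
  expect_error(srmr(diag(c(0, 1)), diag(2)), "diagonal")
})

test_that("R-squared reproduces the tabulated explained-variance values", {
  expect_equal(round(unname(r_squared(0.800, 1.001, 0.357)), 3), 0.642)
  expect_equal(round(unname(r_squared(0.800, 1.985, 0.791)), 3), 0.616)
  expect_equal(unname(r_squared(0.7, 2, 0)), 1)
  # vectorized over indicators of a fitted level
  lp <- level_params(matrix(c(1, 0.9), 2, 1), 0.5, c(0.5, 0.19))
  expect_equal(unname(r_squared(lp)), c(0.5 / 1, 0.405 / 0.595),
               tolerance = 1e-12)
})

test_that("level-specific statistics come from partially saturated fits", {
  dec <- compute_decomposition(random_dataset_strong(62, p = 4, G = 30,
                                                     n = 15))
  w <- factor_pattern(list(f = dec$labels))
  b <- factor_pattern(list(g = dec$labels))
  ws <- level_specific_fit(w, dec, "within_specific")
  expect_equal(ws$stats$df,
               degrees_of_freedom(build_model("max_mcfa", w),
                                  "within_specific"))
  bs <- level_specific_fit(b, dec, "between_specific")
  expect_equal(bs$stats$df, 4 * 5 / 2 - (3 + 1 + 4))
  expect_s3_class(bs$stats, "mlcfa_fitstats")
  # a fit whose other level is not saturated cannot claim level-specific fit
  mc <- fit_model(build_model("mcfa", w, b), dec, se = FALSE)
  expect_error(fit_statistics(mc, dec, "between_specific"),
               "level_specific_fit")
})

test_that("within-specific chi-square is calibrated under a true model", {
  # correctly specified within model: the within-specific statistic is
  # chi-square distributed with its df; check mean and rejection rate
  p <- 4
  lab <- paste0("y", 1:p)
  pop <- two_level_population(
    within = level_params(matrix(0.8, p, 1, dimnames = list(lab, "f")),
                          1, rep(0.36, p)),
    between = level_params(matrix(0.5, p, 1, dimnames = list(lab, "f")),
                           1, rep(0.2, p)),
    G = 40, n = 8)
  w <- factor_pattern(list(f = lab))
  model <- build_model("max_mcfa", w)
  df <- degrees_of_freedom(model, "within_specific")
  reps <- 400
  chi2 <- rejected <- numeric(reps)
  for (r in seq_len(reps)) {
    dec <- compute_decomposition(generate_dataset(pop, seed = 5000 + r))
    fit <- fit_model(model, dec, se = FALSE)
    cs <- chi_square(fit)
    chi2[r] <- cs$chi2
    rejected[r] <- cs$p_value < 0.05
  }
  # mean within 3 MC SEs of df
  expect_lt(abs(mean(chi2) - df), 3 * sd(chi2) / sqrt(reps))
  rate <- mean(rejected)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})
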