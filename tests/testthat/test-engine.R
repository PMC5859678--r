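test_that("implied covariance is the factor-analytic structure", {
  expect_equal(implied_covariance(level_params(1, 1, 0.36))[1, 1], 1.36)
  lp0 <- level_params(matrix(0, 3, 1), 1, c(0.2, 0.3, 0.4))
  expect_equal(implied_covariance(lp0), diag(c(0.2, 0.3, 0.4)))
  # unit-variance factor, loadings .8, residuals .36: unit diagonal,
  # off-diagonals .64
  lp <- level_params(matrix(0.8, 9, 1), 1, rep(0.36, 9))
  S <- implied_covariance(lp)
  expect_equal(diag(S), rep(1, 9))
  expect_equal(S[1, 2], 0.64)
})

test_that("the ML discrepancy has its closed-form scalar values", {
  S <- matrix(c(1, .3, .3, 1), 2)
  expect_equal(f_ml(S, S), 0)
  expect_equal(f_ml(matrix(2), matrix(1)), 2 - log(2) - 1)
  expect_equal(f_ml(matrix(1), matrix(2)), log(2) + 0.5 - 1)
  expect_gt(f_ml(S, diag(2)), 0)
  expect_error(f_ml(S, matrix(c(1, 2, 2, 1), 2)), "smallest eigenvalue")
})

test_that("the MUML discrepancy weights its two brackets", {
  dec <- compute_decomposition(toy_dataset())
  expect_equal(f_muml(dec, matrix(2), matrix(3)), 2 * (1 - log(2)))
  # exact fit: Sigma_W = S_PW, Sigma_B = (S_B - S_PW)/c
  expect_equal(f_muml(dec, dec$S_PW, (dec$S_B - dec$S_PW) / dec$c), 0)
})

test_that("just-identified CFA reproduces its moment solution", {
  S <- matrix(0.48, 3, 3); diag(S) <- 1
  dimnames(S) <- list(c("a", "b", "c"), c("a", "b", "c"))
  fit <- fit_model(build_model("cfa",
                               factor_pattern(list(f = c("a", "b", "c")))),
                   list(S = S, N = 100))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["within.lambda[b~f]"]), 1,
               tolerance = 1e-6)
  expect_equal(unname(fit$estimates["within.lambda[c~f]"]), 1,
               tolerance = 1e-6)
  expect_equal(unname(fit$estimates["within.psi[f,f]"]), 0.48,
               tolerance = 1e-6)
  expect_equal(unname(fit$estimates[paste0("within.theta[", c("a","b","c"),
                                           "]")]),
               rep(0.52, 3), tolerance = 1e-6)
  expect_equal(fit$F_min, 0, tolerance = 1e-10)
})

test_that("the saturated two-level model fits exactly", {
  dec <- compute_decomposition(random_dataset(21, p = 3, G = 10))
  fit <- fit_model(build_model("saturated", indicators = dec$labels),
                   dec, se = FALSE)
  expect_equal(fit$F_min, 0, tolerance = 1e-8)
  expect_equal(fit$implied_within, unname(dec$S_PW) + 0 * fit$implied_within,
               ignore_attr = TRUE, tolerance = 1e-7)
  expect_equal(fit$implied_between,
               (dec$S_B - dec$S_PW) / dec$c,
               ignore_attr = TRUE, tolerance = 1e-7)
})

test_that("F_min is invariant to indicator permutation", {
  ds <- random_dataset_strong(31, p = 4)
  dec <- compute_decomposition(ds)
  lab <- dec$labels
  w <- factor_pattern(list(f = lab))
  fit <- fit_model(build_model("max_mcfa", w), dec, se = FALSE)
  perm <- c(3, 1, 4, 2)
  ds2 <- multilevel_dataset(ds$values[, perm], ds$cluster_id, ds$case_id)
  w2 <- factor_pattern(list(f = lab[perm]))
  fit2 <- fit_model(build_model("max_mcfa", w2),
                    compute_decomposition(ds2), se = FALSE)
  expect_equal(fit2$F_min, fit$F_min, tolerance = 1e-6)
  # estimates permute consistently: residual variances follow indicators
  expect_equal(unname(fit2$estimates[sprintf("within.theta[%s]", lab)]),
               unname(fit$estimates[sprintf("within.theta[%s]", lab)]),
               tolerance = 1e-5)
})

test_that("maximum-model fit equals the pooled-within one-level fit", {
  dec <- compute_decomposition(random_dataset_strong(32, p = 4))
  w <- factor_pattern(list(f = dec$labels))
  mx <- fit_model(build_model("max_mcfa", w), dec, se = FALSE)
  # fit the same within model to S_PW alone with weight N - G
  one <- fit_model(build_model("cfa", w),
                   list(S = dec$S_PW, N = dec$N - dec$G + 1), se = FALSE)
  expect_equal(chi_square(mx)$chi2, chi_square(one)$chi2,
               tolerance = 1e-6)
  wlab <- mx$map$label[mx$map$level == "within"]
  expect_equal(mx$estimates[wlab], one$estimates[wlab], tolerance = 1e-6)
})

test_that("MUML equals an independently coded two-group ML fit", {
  dec <- compute_decomposition(random_dataset_strong(33, p = 3, G = 30,
                                                     n = 20))
  w <- factor_pattern(list(f = dec$labels))
  b <- factor_pattern(list(g = dec$labels))
  fit <- fit_model(build_model("mcfa", w, b), dec, se = FALSE)
  or <- oracle_fit_mcfa(dec)
  expect_equal(fit$F_min, or$value, tolerance = 1e-6)
  expect_equal(unname(fit$estimates), unname(or$par), tolerance = 1e-4)
  # cross-evaluation: the oracle objective at the engine's estimates
  # equals the engine's minimum
  expect_equal(or$obj(unname(fit$estimates)), fit$F_min,
               tolerance = 1e-8)
})

test_that("standard errors match the closed-form scalar case and scale", {
  s2 <- 2.5; N <- 50
  fit <- fit_model(build_model("cfa", within = "saturated",
                               indicators = "y"),
                   list(S = matrix(s2, dimnames = list("y", "y")), N = N))
  expect_equal(unname(fit$se), sqrt(2 * s2^2 / (N - 1)),
               tolerance = 1e-6)

  # doubling every count roughly halves squared SEs
  ds <- random_dataset_strong(34, p = 4, G = 30, n = 10)
  dec1 <- compute_decomposition(ds)
  ds2 <- multilevel_dataset(rbind(ds$values, ds$values),
                            c(ds$cluster_id,
                              paste0("copy_", ds$cluster_id)))
  dec2 <- compute_decomposition(ds2)
  w <- factor_pattern(list(f = dec1$labels))
  f1 <- fit_model(build_model("max_mcfa", w), dec1)
  f2 <- fit_model(build_model("max_mcfa", w), dec2)
  wl <- f1$map$label[f1$map$level == "within"]
  ratio <- (f1$se[wl] / f2$se[wl])^2
  expect_true(all(abs(ratio - 2) < 0.25))
})

test_that("a Heywood solution is flagged, not clamped", {
  # a sample matrix engineered so one residual variance goes negative:
  # indicator a correlates more strongly with b and c than b and c do
  # with each other
  S <- matrix(c(1, .9, .9,
                .9, 1, .5,
                .9, .5, 1), 3, 3,
              dimnames = list(c("a","b","c"), c("a","b","c")))
  expect_warning(
    fit <- fit_model(build_model("cfa",
                                 factor_pattern(list(f = c("a","b","c")))),
                     list(S = S, N = 200), se = FALSE),
    "Heywood")
  expect_true(any(fit$estimates[fit$map$mat == "theta"] < 0))
})
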