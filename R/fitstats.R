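#' Chi-square test statistic of a fitted model
#'
#' For two-level (MUML) fits the minimized discrepancy already carries the
#' `G` and `N - G` weights, so the statistic is `F_min` itself; one-level
#' fits use the Wishart convention `(N - 1) * F_min`. The p-value is from
#' the central chi-square distribution at the model's overall df; for a
#' just-identified model (df 0) the p-value is undefined (`NA`).
#'
#' @param fit a `mlcfa_fit`.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
chi_square <- function(fit) {
  stopifnot(inherits(fit, "mlcfa_fit"))
  chi2 <- if (fit$model$two_level) fit$F_min else (fit$N - 1) * fit$F_min
  chi2 <- max(chi2, 0)
  df <- degrees_of_freedom(fit$model, "overall")
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  list(chi2 = chi2, df = df, p_value = p)
}

#' Comparative fit index
#'
#' `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)` with
#' the baseline an independence model of the same scope. If the baseline
#' is not worse than the target model the denominator is zero and CFI is
#' 1 with a warning.
#'
#' @param chi2,df target model statistic and df.
#' @param chi2_baseline,df_baseline independence-baseline statistic/df.
#' @return CFI in \[0, 1\].
#' @export
cfi <- function(chi2, df, chi2_baseline, df_baseline) {
  num <- max(chi2 - df, 0)
  den <- max(chi2_baseline - df_baseline, chi2 - df, 0)
  if (den <= 0) {
    if (num > 0) warning("baseline model not worse than target; CFI set to 1",
                         call. = FALSE)
    return(1)
  }
  min(max(1 - num / den, 0), 1)
}

#' Root mean square error of approximation
#'
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df * (N - 1)))` with `N` the total
#' number of lowest-level cases for every scope (including level-specific
#' statistics). Undefined (`NA`) when `df = 0`.
#'
#' @param chi2,df model chi-square and df.
#' @param N total sample size.
#' @return RMSEA (>= 0) or `NA` when df is 0.
#' @export
rmsea <- function(chi2, df, N) {
  if (df < 1) return(NA_real_)
  sqrt(max(chi2 - df, 0) / (df * (N - 1)))
}

#' Standardized root mean square residual
#'
#' Root mean square of the standardized residuals over the unique
#' elements: `sqrt(mean_{i<=j} [(s_ij - sigma_ij)/sqrt(s_ii s_jj)]^2)`.
#' Standardization uses the sample matrix diagonals.
#'
#' @param S sample covariance matrix.
#' @param Sigma_hat implied covariance matrix of matching dimension.
#' @return SRMR (>= 0).
#' @export
srmr <- function(S, Sigma_hat) {
  S <- as.matrix(S); Sigma_hat <- as.matrix(Sigma_hat)
  if (any(diag(S) <= 0))
    stop("zero or negative diagonal in S", call. = FALSE)
  d <- sqrt(diag(S))
  R <- (S - Sigma_hat) / tcrossprod(d)
  sqrt(mean(R[upper.tri(R, diag = TRUE)]^2))
}

#' Per-indicator explained variance
#'
#' `R2_j = (Lambda Psi Lambda')_jj / [(Lambda Psi Lambda')_jj + Theta_jj]`
#' for one level of a fitted factor model: the share of an indicator's
#' level-specific variance accounted for by the factors.
#'
#' @param lambda loading matrix, [level_params()] object, or for the
#'   scalar convenience form a single loading.
#' @param psi factor covariance (ignored when `lambda` is `level_params`).
#' @param theta residual variance(s) (ignored likewise).
#' @return named vector of R-squared values, one per indicator.
#' @examples
#' r_squared(0.800, 1.001, 0.357)  # 0.642
#' @export
r_squared <- function(lambda, psi = NULL, theta = NULL) {
  lp <- if (inherits(lambda, "level_params")) lambda
        else level_params(lambda, psi, theta)
  common <- diag(lp$Lambda %*% lp$Psi %*% t(lp$Lambda))
  tot <- common + diag(as.matrix(lp$Theta))
  out <- ifelse(tot > 0, common / tot, NA_real_)
  names(out) <- rownames(lp$Lambda)
  out
}

baseline_model <- function(scope, indicators) {
  switch(scope,
    overall_one = build_model("cfa", within = "independence",
                              indicators = indicators),
    overall_two = build_model("independence", indicators = indicators),
    within_specific = build_model("mcfa", within = "independence",
                                  between = "saturated",
                                  indicators = indicators),
    between_specific = build_model("mcfa", within = "saturated",
                                   between = "independence",
                                   indicators = indicators))
}

#' Fit statistics for a fitted model at a given scope
#'
#' Assembles chi-square, df, p, CFI, RMSEA and SRMR. The scope controls
#' which sample/implied matrices enter the SRMR and which independence
#' baseline is used for CFI:
#' \describe{
#'   \item{overall}{one-level models compare `S_T` with the implied total
#'     matrix; two-level models pool both brackets, with SRMR averaged
#'     over the within (`S_PW` vs `Sigma_W`) and between
#'     (`S_B` vs `Sigma_W + c Sigma_B`) scopes.}
#'   \item{within_specific}{statistics of the maximum model carrying this
#'     fit's within structure; SRMR compares `S_PW` with `Sigma_W`.}
#'   \item{between_specific}{statistics of the partially saturated model
#'     carrying this fit's between structure; SRMR compares `S_B` with
#'     `Sigma_W + c Sigma_B`.}
#' }
#' Level-specific scopes require the corresponding partially saturated
#' fit; use [level_specific_fit()] to produce them from a decomposition.
#'
#' @param fit a `mlcfa_fit`.
#' @param decomp the `mlcfa_decomp` the model was fitted to (used for the
#'   baseline fit and SRMR); optional for one-level fits, which reuse the
#'   stored sample matrix.
#' @param scope `"overall"`, `"within_specific"` or `"between_specific"`.
#' @return An object of class `mlcfa_fitstats`: `scope`, `chi2`, `df`,
#'   `p_value`, `cfi`, `rmsea`, `srmr`.
#' @export
fit_statistics <- function(fit, decomp = NULL,
                           scope = c("overall", "within_specific",
                                     "between_specific")) {
  stopifnot(inherits(fit, "mlcfa_fit"))
  scope <- match.arg(scope)
  model <- fit$model
  if (is.null(decomp) && inherits(fit$data_used, "mlcfa_decomp"))
    decomp <- fit$data_used
  cs <- chi_square(fit)
  chi2 <- cs$chi2
  if (scope == "overall") {
    df <- cs$df
  } else {
    if (!model$two_level)
      stop("level-specific scope undefined for a one-level model",
           call. = FALSE)
    other <- if (scope == "within_specific") model$between else model$within
    if (!identical(other, "saturated"))
      stop(scope, " statistics require the other level to be saturated; ",
           "use level_specific_fit()", call. = FALSE)
    df <- degrees_of_freedom(model, scope)
  }
  ind <- model$indicators
  # baseline
  if (!model$two_level) {
    bl_model <- baseline_model("overall_one", ind)
    bl <- fit_model(bl_model, list(S = fit$data_used$S_T, N = fit$N),
                    se = FALSE)
  } else {
    key <- if (scope == "overall") "overall_two" else scope
    bl <- fit_model(baseline_model(key, ind), decomp, se = FALSE)
  }
  blc <- chi_square(bl)
  # SRMR
  sr <- if (!model$two_level) {
    srmr(fit$data_used$S_T, fit$implied_total)
  } else if (scope == "within_specific") {
    srmr(decomp$S_PW, fit$implied_within)
  } else if (scope == "between_specific") {
    srmr(decomp$S_B,
         fit$implied_within + decomp$c * fit$implied_between)
  } else {
    mean(c(srmr(decomp$S_PW, fit$implied_within),
           srmr(decomp$S_B,
                fit$implied_within + decomp$c * fit$implied_between)))
  }
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  structure(list(scope = scope, chi2 = chi2, df = df, p_value = p,
                 cfi = cfi(chi2, df, blc$chi2, blc$df),
                 rmsea = rmsea(chi2, df, fit$N),
                 srmr = sr),
            class = "mlcfa_fitstats")
}

#' Level-specific fit of a factor pattern
#'
#' Isolates the misfit attributable to one level by saturating the other:
#' the within-specific statistics are those of the maximum model
#' (hypothesized within pattern, saturated between), the between-specific
#' statistics those of the partially saturated model (saturated within,
#' hypothesized between pattern).
#'
#' @param pattern a [factor_pattern()] for the level of interest (or a
#'   `mlcfa_model` whose relevant level is extracted).
#' @param decomp a `mlcfa_decomp`.
#' @param scope `"within_specific"` or `"between_specific"`.
#' @return list with elements `fit` (the partially saturated
#'   `mlcfa_fit`) and `stats` (`mlcfa_fitstats`).
#' @export
level_specific_fit <- function(pattern, decomp,
                               scope = c("within_specific",
                                         "between_specific")) {
  scope <- match.arg(scope)
  if (inherits(pattern, "mlcfa_model"))
    pattern <- if (scope == "within_specific") pattern$within
               else pattern$between
  model <- if (scope == "within_specific")
    build_model("max_mcfa", within = pattern)
  else
    build_model("ps_between", between = pattern)
  fit <- fit_model(model, decomp)
  list(fit = fit, stats = fit_statistics(fit, decomp, scope))
}

#' @export
print.mlcfa_fitstats <- function(x, ...) {
  cat(sprintf(
    "[%s] chi2(df) = %.3f(%d), p = %s, CFI = %.3f, RMSEA = %s, SRMR = %.3f\n",
    x$scope, x$chi2, x$df,
    if (is.na(x$p_value)) "NA" else format(round(x$p_value, 3)),
    x$cfi,
    if (is.na(x$rmsea)) "NA" else format(round(x$rmsea, 3)),
    x$srmr))
  invisible(x)
}
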