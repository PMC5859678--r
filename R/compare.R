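#' Relative difference between CFA and multilevel estimates
#'
#' Congruence diagnostic for step 1 of the three-step workflow: the
#' percentage difference of a one-level CFA estimate from the
#' corresponding within-level reference estimate (maximum model or MCFA),
#' expressed relative to the CFA estimate:
#' `100 * (est_cfa - est_ref) / est_cfa`. Large values signal that the
#' one-level analysis conflates within- and between-level structure.
#'
#' @param est_cfa one-level CFA estimate(s); must be nonzero.
#' @param est_ref within-level reference estimate(s).
#' @return percentage difference(s); `NA` with a warning where the
#'   denominator is zero.
#' @examples
#' relative_difference(1.071, 0.901)  # 15.87
#' @export
relative_difference <- function(est_cfa, est_ref) {
  out <- 100 * (est_cfa - est_ref) / est_cfa
  zero <- est_cfa == 0
  if (any(zero, na.rm = TRUE)) {
    warning("zero CFA estimate; relative difference undefined",
            call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Wald-type t contrast between two model estimates
#'
#' Descriptive congruence index treating the two models' estimates as
#' independent: `t = (est1 - est2) / sqrt(se1^2 + se2^2)` with
#' `df = n1 + n2 - 2` and a two-sided p-value from the t distribution.
#' Because both estimates come from the same data this is not a formal
#' test; it mirrors the conventional two-sample contrast used to flag
#' incongruent estimates.
#'
#' @param est1,se1,n1 estimate, standard error and sample size of model 1.
#' @param est2,se2,n2 same for model 2.
#' @return list with `t`, `df`, `p_value`.
#' @examples
#' wald_t(1.071, 0.056, 400, 0.901, 0.064, 400)  # t close to 2.00
#' @export
wald_t <- function(est1, se1, n1, est2, se2, n2) {
  if (any(c(se1, se2) <= 0) || anyNA(c(se1, se2)))
    stop("standard errors must be positive", call. = FALSE)
  if (any(c(n1, n2) < 2)) stop("sample sizes must be >= 2", call. = FALSE)
  t <- (est1 - est2) / sqrt(se1^2 + se2^2)
  df <- n1 + n2 - 2
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Tabulate competing models side by side
#'
#' Builds the three-model comparison report: a fit block (one row of
#' chi-square(df), CFI, RMSEA, SRMR per model, each at its reporting
#' scope), an aligned parameter block (estimate and SE per model, rows
#' keyed by level and parameter, absent cells `NA`), and a diagnostics
#' block of congruence indices ([relative_difference()] and [wald_t()])
#' for every free within-level loading present in both the one-level CFA
#' and the multilevel reference (maximum model if present, else MCFA),
#' plus a count of contrasts with `|t| > 1.96`.
#'
#' Reporting scopes follow the tabulation convention of the workflow: the
#' one-level CFA reports overall fit, a maximum model reports
#' within-specific fit, and an MCFA reports between-specific fit (its
#' within misfit being already screened at the maximum-model step).
#'
#' @param fits named list of `mlcfa_fit` objects; names such as `"cfa"`,
#'   `"max_mcfa"`, `"mcfa"` (additional models, e.g. a misspecified MCFA,
#'   simply add columns).
#' @param decomp the shared `mlcfa_decomp` (for fit statistics).
#' @return An object of class `mlcfa_comparison` with components
#'   `fit_block`, `param_block`, `diagnostics`, `n_flagged`.
#' @export
build_comparison <- function(fits, decomp = NULL) {
  if (!length(fits) || is.null(names(fits)))
    stop("'fits' must be a non-empty named list", call. = FALSE)
  ind <- lapply(fits, function(f) f$model$indicators)
  if (length(unique(ind)) != 1)
    stop("all fits must share the same indicator set and order",
         call. = FALSE)

  report_scope <- function(f) {
    if (!f$model$two_level) "overall"
    else if (identical(f$model$between, "saturated")) "within_specific"
    else if (identical(f$model$within, "saturated")) "between_specific"
    else "between_specific"
  }
  fb <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    sc <- report_scope(f)
    st <- if (sc == "between_specific" &&
              !identical(f$model$within, "saturated")) {
      # the tabulated MCFA row is the between-specific statistic of the
      # partially saturated model sharing this fit's between structure
      level_specific_fit(f$model, decomp, "between_specific")$stats
    } else fit_statistics(f, decomp, sc)
    data.frame(model = nm, scope = st$scope, chi2 = st$chi2, df = st$df,
               p_value = st$p_value, cfi = st$cfi, rmsea = st$rmsea,
               srmr = st$srmr, stringsAsFactors = FALSE)
  })
  fit_block <- do.call(rbind, fb)

  keys <- unique(unlist(lapply(fits, function(f) f$map$label)))
  param_block <- data.frame(parameter = keys, stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    param_block[[paste0(nm, "_est")]] <-
      unname(f$estimates[match(keys, f$map$label)])
    param_block[[paste0(nm, "_se")]] <-
      unname(f$se[match(keys, f$map$label)])
  }

  diagnostics <- NULL; n_flagged <- NA_integer_
  ref_name <- intersect(c("max_mcfa", "mcfa"), names(fits))[1]
  if ("cfa" %in% names(fits) && !is.na(ref_name)) {
    cfa <- fits[["cfa"]]; ref <- fits[[ref_name]]
    lam <- cfa$map$mat == "lambda"
    shared <- intersect(cfa$map$label[lam], ref$map$label)
    if (length(shared)) {
      e1 <- cfa$estimates[shared]; s1 <- cfa$se[shared]
      e2 <- ref$estimates[shared]; s2 <- ref$se[shared]
      rd <- relative_difference(e1, e2)
      tt <- rep(NA_real_, length(shared))
      pp <- rep(NA_real_, length(shared))
      ok <- !is.na(s1) & !is.na(s2) & s1 > 0 & s2 > 0
      if (any(ok)) {
        wt <- wald_t(e1[ok], s1[ok], cfa$N, e2[ok], s2[ok], ref$N)
        tt[ok] <- wt$t; pp[ok] <- wt$p_value
      }
      diagnostics <- data.frame(parameter = shared,
                                cfa = unname(e1),
                                reference = unname(e2),
                                rel_diff_pct = unname(rd),
                                t = unname(tt),
                                df = cfa$N + ref$N - 2,
                                p_value = unname(pp),
                                stringsAsFactors = FALSE)
      n_flagged <- sum(abs(tt) > 1.96, na.rm = TRUE)
    }
  }
  structure(list(fit_block = fit_block, param_block = param_block,
                 diagnostics = diagnostics, n_flagged = n_flagged),
            class = "mlcfa_comparison")
}

#' @export
print.mlcfa_comparison <- function(x, digits = 3, ...) {
  cat("Model fit statistics\n")
  fb <- x$fit_block
  fb$chi2_df <- sprintf("%.3f(%d)", fb$chi2, fb$df)
  print(fb[, c("model", "scope", "chi2_df", "cfi", "rmsea", "srmr")],
        digits = digits, row.names = FALSE)
  if (!is.null(x$diagnostics)) {
    cat("\nCongruence diagnostics (CFA vs within-level reference)\n")
    print(x$diagnostics, digits = digits, row.names = FALSE)
    cat(sprintf("range of relative differences: %.2f%% to %.2f%%; %d contrast(s) with |t| > 1.96\n",
                min(x$diagnostics$rel_diff_pct, na.rm = TRUE),
                max(x$diagnostics$rel_diff_pct, na.rm = TRUE),
                x$n_flagged))
  }
  invisible(x)
}
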