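#' Define a factor pattern for one level
#'
#' A factor pattern lists which indicators load on which factors. By the
#' marker-variable convention the first indicator of each factor has its
#' loading fixed (default 1.0) to set the latent scale; all other listed
#' loadings are free, unlisted loadings are zero. Factor variances and all
#' factor covariances are free, and residual variances are free and
#' uncorrelated. Cross-loadings are allowed simply by listing an indicator
#' under several factors (it is a marker for at most one of them).
#'
#' @param factors named list: factor name -> character vector of indicator
#'   names, in order (the first is the marker).
#' @param indicators full indicator vector, fixing the order shared across
#'   levels; defaults to the indicators in order of first appearance.
#' @param marker_value fixed value of each marker loading (scalar or one
#'   value per factor).
#' @return An object of class `factor_pattern` with a p x m `loadings`
#'   template (`NA` = free, numeric = fixed, 0 = excluded).
#' @examples
#' factor_pattern(list(f1 = c("wordst", "cards", "matrix"),
#'                     f2 = c("figure", "animal", "occpat")))
#' @export
factor_pattern <- function(factors, indicators = NULL, marker_value = 1) {
  if (!is.list(factors) || is.null(names(factors)) ||
      any(!nzchar(names(factors))))
    stop("'factors' must be a named list of indicator vectors",
         call. = FALSE)
  if (any(lengths(factors) < 1))
    stop("every factor needs at least one indicator", call. = FALSE)
  all_ind <- unique(unlist(factors, use.names = FALSE))
  if (is.null(indicators)) indicators <- all_ind
  unknown <- setdiff(all_ind, indicators)
  if (length(unknown))
    stop("unknown indicator label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  m <- length(factors)
  marker_value <- rep_len(marker_value, m)
  p <- length(indicators)
  L <- matrix(0, p, m, dimnames = list(indicators, names(factors)))
  marked <- character(0)
  for (k in seq_len(m)) {
    ind <- factors[[k]]
    L[ind, k] <- NA_real_
    # marker: first listed indicator not already serving as a marker
    mk <- setdiff(ind, marked)
    if (!length(mk))
      stop("no free indicator left to act as marker for factor ",
           names(factors)[k], call. = FALSE)
    L[mk[1], k] <- marker_value[k]
    marked <- c(marked, mk[1])
  }
  structure(list(factors = factors, indicators = indicators,
                 loadings = L, m = m, p = p,
                 marker_value = marker_value),
            class = "factor_pattern")
}

level_token <- function(x) {
  is.character(x) && length(x) == 1 &&
    x %in% c("saturated", "independence")
}

#' Build a model definition
#'
#' The five model kinds of the three-step multilevel CFA workflow:
#' \describe{
#'   \item{`cfa`}{one-level CFA fitted to the total covariance `S_T`,
#'     ignoring clustering.}
#'   \item{`mcfa`}{two-level model with hypothesized within and between
#'     factor patterns, fitted by MUML.}
#'   \item{`max_mcfa`}{the "maximum" model: hypothesized within pattern,
#'     saturated between level (all between covariances free), so only
#'     within-level misfit contributes to the discrepancy.}
#'   \item{`ps_between`}{partially saturated counterpart: saturated within
#'     level, hypothesized between pattern; isolates between-level misfit.}
#'   \item{`saturated` / `independence`}{two-level reference models (exact
#'     fit with df 0; all covariances zero). One-level versions arise by
#'     passing the token as `within` with `kind = "cfa"`.}
#' }
#'
#' @param kind one of `"cfa"`, `"mcfa"`, `"max_mcfa"`, `"ps_between"`,
#'   `"saturated"`, `"independence"`.
#' @param within a [factor_pattern()] or the token `"saturated"` /
#'   `"independence"` (ignored for kinds that force a token).
#' @param between as `within`, for the between level; must reference the
#'   same indicators in the same order.
#' @param indicators indicator order, required when both levels are tokens.
#' @return An object of class `mlcfa_model`.
#' @export
build_model <- function(kind = c("cfa", "mcfa", "max_mcfa", "ps_between",
                                 "saturated", "independence"),
                        within = NULL, between = NULL,
                        indicators = NULL) {
  kind <- match.arg(kind)
  if (kind == "max_mcfa") between <- "saturated"
  if (kind == "ps_between") within <- "saturated"
  if (kind == "saturated") within <- between <- "saturated"
  if (kind == "independence" && is.null(between)) between <- "independence"
  if (kind == "independence" && is.null(within)) within <- "independence"
  two_level <- kind != "cfa"
  if (kind == "cfa") between <- NULL
  if (is.null(within))
    stop("'within' specification required for kind '", kind, "'",
         call. = FALSE)
  if (two_level && is.null(between))
    stop("'between' specification required for kind '", kind, "'",
         call. = FALSE)

  get_ind <- function(x) if (inherits(x, "factor_pattern")) x$indicators
  iw <- get_ind(within); ib <- get_ind(between)
  if (!is.null(iw) && !is.null(ib) && !identical(iw, ib))
    stop("between/within indicator order mismatch:\n  within:  ",
         paste(iw, collapse = ", "), "\n  between: ",
         paste(ib, collapse = ", "), call. = FALSE)
  indicators <- if (!is.null(iw)) iw else if (!is.null(ib)) ib
                else indicators
  if (is.null(indicators))
    stop("'indicators' required when no factor pattern is supplied",
         call. = FALSE)
  chk <- function(x, side) {
    if (is.null(x) || level_token(x)) return(invisible())
    if (!inherits(x, "factor_pattern"))
      stop(side, " must be a factor_pattern or 'saturated'/'independence'",
           call. = FALSE)
  }
  chk(within, "within"); chk(between, "between")
  model <- structure(list(kind = kind, within = within, between = between,
                          indicators = indicators,
                          p = length(indicators),
                          two_level = two_level),
                     class = "mlcfa_model")
  if (degrees_of_freedom(model, "overall") < 0)
    stop("model not identified by counting: ",
         free_parameter_count(model),
         " free parameters exceed the fitted moments", call. = FALSE)
  model
}

level_free_count <- function(spec, p) {
  if (is.null(spec)) return(0L)
  if (level_token(spec))
    return(if (spec == "saturated") p * (p + 1) / 2 else p)
  free_load <- sum(is.na(spec$loadings))
  m <- spec$m
  free_load + m * (m + 1) / 2 + p
}

#' Count free parameters of a model
#'
#' For a factor-pattern level: free loadings plus `m(m+1)/2` factor
#' (co)variances plus `p` residual variances. A saturated level has
#' `p(p+1)/2` free covariance elements, an independence level `p` free
#' variances.
#'
#' @param model a `mlcfa_model`.
#' @return integer count.
#' @export
free_parameter_count <- function(model) {
  stopifnot(inherits(model, "mlcfa_model"))
  as.integer(level_free_count(model$within, model$p) +
             level_free_count(model$between, model$p))
}

#' Degrees of freedom, overall or level-specific
#'
#' Fitted moments are `p(p+1)/2` per level (one level for `cfa`, two
#' otherwise); overall df is moments minus free parameters. Level-specific
#' df saturates the other level: `within_specific` df equals the df of the
#' maximum model (and hence of the one-level CFA with the same within
#' pattern), `between_specific` df equals `p(p+1)/2` minus the between
#' free-parameter count. df is data-independent.
#'
#' @param model a `mlcfa_model`.
#' @param scope `"overall"`, `"within_specific"` or `"between_specific"`.
#' @return integer df (negative df raises an unidentifiable-model error,
#'   except inside [build_model()] counting checks).
#' @export
degrees_of_freedom <- function(model,
                               scope = c("overall", "within_specific",
                                         "between_specific")) {
  stopifnot(inherits(model, "mlcfa_model"))
  scope <- match.arg(scope)
  p <- model$p
  mom1 <- p * (p + 1) / 2
  df <- switch(scope,
    overall = (if (model$two_level) 2 else 1) * mom1 -
      free_parameter_count(model),
    within_specific = mom1 - level_free_count(model$within, p),
    between_specific = {
      if (is.null(model$between))
        stop("between_specific df undefined for a one-level model",
             call. = FALSE)
      mom1 - level_free_count(model$between, p)
    })
  as.integer(df)
}

#' @export
print.factor_pattern <- function(x, ...) {
  cat("Factor pattern:", x$m, "factor(s),", x$p, "indicators\n")
  for (k in seq_len(x$m))
    cat("  ", names(x$factors)[k], ": ",
        paste(x$factors[[k]], collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' @export
print.mlcfa_model <- function(x, ...) {
  lvl <- function(s) {
    if (is.null(s)) "-" else if (level_token(s)) s
    else paste0(s$m, "-factor pattern")
  }
  cat("Model [", x$kind, "]: within = ", lvl(x$within),
      ", between = ", lvl(x$between), "\n", sep = "")
  cat("  ", free_parameter_count(x), " free parameters, overall df = ",
      degrees_of_freedom(x, "overall"), "\n", sep = "")
  invisible(x)
}
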