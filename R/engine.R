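#' Level parameter matrices
#'
#' Numeric loading, factor-covariance and residual matrices for one level
#' of a factor model. Used both for fitted solutions and for simulation
#' populations.
#'
#' @param Lambda p x m numeric loading matrix (a vector is taken as a
#'   single-factor column).
#' @param Psi m x m symmetric factor covariance matrix (a scalar/vector is
#'   expanded to a diagonal).
#' @param Theta p x p residual covariance matrix, or a length-p vector of
#'   residual variances (expanded to a diagonal).
#' @return An object of class `level_params`.
#' @export
level_params <- function(Lambda, Psi, Theta) {
  Lambda <- as.matrix(Lambda)
  if (length(Psi) == 1 || is.null(dim(Psi))) Psi <- diag(as.numeric(Psi),
                                                         ncol(Lambda))
  Psi <- as.matrix(Psi)
  if (is.null(dim(Theta))) Theta <- diag(as.numeric(Theta), nrow(Lambda))
  Theta <- as.matrix(Theta)
  if (ncol(Lambda) != ncol(Psi) || nrow(Psi) != ncol(Psi))
    stop("Psi must be m x m with m = ncol(Lambda)", call. = FALSE)
  if (any(dim(Theta) != nrow(Lambda)))
    stop("Theta must be p x p with p = nrow(Lambda)", call. = FALSE)
  if (max(abs(Psi - t(Psi))) > 1e-12)
    stop("Psi must be symmetric", call. = FALSE)
  structure(list(Lambda = Lambda, Psi = Psi, Theta = Theta),
            class = "level_params")
}

#' Model-implied covariance matrix
#'
#' The factor-analytic structure `Sigma = Lambda Psi Lambda' + Theta`.
#'
#' @param params a [level_params()] object.
#' @return symmetric p x p matrix.
#' @examples
#' implied_covariance(level_params(0.8, 1, 0.36))  # 1.0
#' @export
implied_covariance <- function(params) {
  stopifnot(inherits(params, "level_params"))
  S <- params$Lambda %*% params$Psi %*% t(params$Lambda) + params$Theta
  (S + t(S)) / 2
}

chol_or_fail <- function(M, what) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(out))
    stop(sprintf("%s is not positive definite (smallest eigenvalue %.3g)",
                 what, min(eigen(M, symmetric = TRUE,
                                 only.values = TRUE)$values)),
         call. = FALSE)
  out
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The normal-theory ML fitting function
#' `F = log|Sigma| + tr(Sigma^-1 S) - log|S| - p`, which is nonnegative
#' and zero iff `S = Sigma`.
#'
#' @param S sample covariance matrix (positive definite).
#' @param Sigma model-implied covariance matrix (positive definite).
#' @return scalar discrepancy.
#' @examples
#' f_ml(matrix(2), matrix(1))  # 2 - log(2) - 1
#' @export
f_ml <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  p <- nrow(S)
  cS <- chol_or_fail(S, "S")
  cSig <- chol_or_fail(Sigma, "Sigma")
  Siginv <- chol2inv(cSig)
  2 * sum(log(diag(cSig))) + sum(Siginv * S) -
    2 * sum(log(diag(cS))) - p
}

#' MUML discrepancy for a two-level model
#'
#' Muthen's limited-information discrepancy treats the scaled between
#' matrix and the pooled within matrix as two "groups":
#' `F = G * F_ML(S_B, Sigma_W + c Sigma_B) + (N - G) * F_ML(S_PW, Sigma_W)`.
#'
#' @param decomp a `mlcfa_decomp`.
#' @param Sigma_W,Sigma_B implied within and between covariance matrices.
#' @return scalar discrepancy (already carrying the G and N - G weights).
#' @export
f_muml <- function(decomp, Sigma_W, Sigma_B) {
  stopifnot(inherits(decomp, "mlcfa_decomp"))
  fb <- tryCatch(f_ml(decomp$S_B, Sigma_W + decomp$c * Sigma_B),
                 error = function(e)
                   stop("between bracket: ", conditionMessage(e),
                        call. = FALSE))
  fw <- tryCatch(f_ml(decomp$S_PW, Sigma_W),
                 error = function(e)
                   stop("within bracket: ", conditionMessage(e),
                        call. = FALSE))
  decomp$G * fb + (decomp$N - decomp$G) * fw
}

## ---- parameter bookkeeping -------------------------------------------

# one row per free parameter: level, mat (lambda/psi/theta/sigma), i, j
param_map_level <- function(spec, level, labels) {
  p <- length(labels)
  if (level_token(spec)) {
    if (spec == "saturated") {
      ij <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
      ij <- ij[order(ij[, "col"], ij[, "row"]), , drop = FALSE]
      return(data.frame(level = level, mat = "sigma",
                        i = ij[, 1], j = ij[, 2],
                        label = sprintf("%s.sigma[%s,%s]", level,
                                        labels[ij[, 1]], labels[ij[, 2]]),
                        stringsAsFactors = FALSE))
    }
    return(data.frame(level = level, mat = "theta", i = seq_len(p),
                      j = seq_len(p),
                      label = sprintf("%s.theta[%s]", level, labels),
                      stringsAsFactors = FALSE))
  }
  L <- spec$loadings
  free <- which(is.na(L), arr.ind = TRUE)
  fn <- names(spec$factors)
  out <- list()
  if (nrow(free))
    out$lambda <- data.frame(level = level, mat = "lambda",
                             i = free[, 1], j = free[, 2],
                             label = sprintf("%s.lambda[%s~%s]", level,
                                             labels[free[, 1]],
                                             fn[free[, 2]]),
                             stringsAsFactors = FALSE)
  m <- spec$m
  ij <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, "col"], ij[, "row"]), , drop = FALSE]
  out$psi <- data.frame(level = level, mat = "psi",
                        i = ij[, 1], j = ij[, 2],
                        label = sprintf("%s.psi[%s,%s]", level,
                                        fn[ij[, 1]], fn[ij[, 2]]),
                        stringsAsFactors = FALSE)
  out$theta <- data.frame(level = level, mat = "theta", i = seq_len(p),
                          j = seq_len(p),
                          label = sprintf("%s.theta[%s]", level, labels),
                          stringsAsFactors = FALSE)
  do.call(rbind, out)
}

param_map <- function(model) {
  maps <- list(param_map_level(model$within, "within", model$indicators))
  if (model$two_level)
    maps <- c(maps, list(param_map_level(model$between, "between",
                                         model$indicators)))
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  out
}

# rebuild one level's matrices from the slice of the parameter vector
level_sigma <- function(spec, theta, map, p) {
  if (level_token(spec)) {
    if (spec == "saturated") {
      S <- matrix(0, p, p)
      S[cbind(map$i, map$j)] <- theta
      S <- S + t(S) - diag(diag(S), p)
      return(list(Sigma = S))
    }
    return(list(Sigma = diag(theta, p), Theta = diag(theta, p)))
  }
  L <- spec$loadings
  lam <- map$mat == "lambda"
  L[cbind(map$i[lam], map$j[lam])] <- theta[lam]
  m <- spec$m
  Psi <- matrix(0, m, m)
  ps <- map$mat == "psi"
  Psi[cbind(map$i[ps], map$j[ps])] <- theta[ps]
  Psi <- Psi + t(Psi) - diag(diag(Psi), m)
  th <- map$mat == "theta"
  Theta <- diag(theta[th], p)
  Sig <- L %*% Psi %*% t(L) + Theta
  list(Sigma = (Sig + t(Sig)) / 2, Lambda = L, Psi = Psi, Theta = Theta)
}

# start values: markers at their fixed value, free loadings 0.7, factor
# variances at half the marker indicator's sample variance, factor
# covariances 0, residual variances at half the sample variances
start_values_level <- function(spec, map, sample_var, sample_cov = NULL) {
  x <- numeric(nrow(map))
  if (level_token(spec)) {
    if (spec == "saturated") {
      x <- sample_cov[cbind(map$i, map$j)]
    } else x <- pmax(sample_var[map$i], 0.05)
    return(x)
  }
  x[map$mat == "lambda"] <- 0.7
  ps <- which(map$mat == "psi")
  for (k in ps) {
    if (map$i[k] == map$j[k]) {
      idx <- which(is.na(spec$loadings[, map$i[k]]) |
                   spec$loadings[, map$i[k]] != 0)
      x[k] <- 0.5 * mean(pmax(sample_var[idx], 0.05))
    } else x[k] <- 0
  }
  x[map$mat == "theta"] <- 0.5 * pmax(sample_var[map$i[map$mat == "theta"]],
                                      0.05)
  x
}

num_gradient <- function(f, x, rel_step = 1e-5) {
  h <- rel_step * pmax(1, abs(x))
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    e <- numeric(length(x)); e[k] <- h[k]
    g[k] <- (f(x + e) - f(x - e)) / (2 * h[k])
  }
  g
}

num_hessian <- function(f, x, rel_step = 1e-4) {
  n <- length(x)
  h <- rel_step * pmax(1, abs(x))
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (k in seq_len(n)) {
    ek <- numeric(n); ek[k] <- h[k]
    H[k, k] <- (f(x + ek) - 2 * f0 + f(x - ek)) / h[k]^2
    if (k < n) for (l in (k + 1):n) {
      el <- numeric(n); el[l] <- h[l]
      H[k, l] <- H[l, k] <-
        (f(x + ek + el) - f(x + ek - el) -
         f(x - ek + el) + f(x - ek - el)) / (4 * h[k] * h[l])
    }
  }
  H
}

f_ml_quiet <- function(S, Sigma, logdetS, p) {
  cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cSig)) return(NA_real_)
  2 * sum(log(diag(cSig))) + sum(chol2inv(cSig) * S) - logdetS - p
}

## ---- fitting ----------------------------------------------------------

#' Fit a model by minimizing the (MU)ML discrepancy
#'
#' One-level kinds minimize the ML discrepancy to `S_T` (the chi-square
#' statistic is `(N - 1) * F_min`, the Wishart convention); two-level
#' kinds minimize the MUML discrepancy [f_muml()], whose minimum is itself
#' the chi-square statistic. Minimization uses `nlminb` (quasi-Newton)
#' with central-difference gradients on the per-observation scale of the
#' discrepancy; the convergence flag requires a scaled gradient norm below
#' 1e-6. Models with a saturated between level are fitted by profiling:
#' for any within structure the between bracket is zeroed exactly by
#' `Sigma_B = (S_B - Sigma_W) / c`, so only the within parameters are
#' iterated (the profile Hessian equals the joint-fit information for the
#' within parameters). Negative residual-variance estimates (Heywood
#' cases) are reported as warnings, never clamped.
#'
#' @param model a `mlcfa_model` from [build_model()].
#' @param data a `mlcfa_decomp` from [compute_decomposition()], or for
#'   one-level kinds a list with elements `S` and `N`.
#' @param se compute standard errors from the numerical Hessian
#'   (default TRUE).
#' @param control optional list: `iter.max`, `eval.max`, `rel.tol`
#'   passed to `nlminb`.
#' @return An object of class `mlcfa_fit`: `estimates` and `se` (named),
#'   `F_min`, `converged`, `n_iter`, `gradient_norm`, implied matrices
#'   (`implied_total`, or `implied_within`/`implied_between`), per-level
#'   `params` ([level_params()] where the level is structured), the
#'   parameter table `map`, and data summaries (`N`, `G`, `c`).
#' @export
fit_model <- function(model, data, se = TRUE, control = list()) {
  stopifnot(inherits(model, "mlcfa_model"))
  ctl <- utils::modifyList(list(iter.max = 1000, eval.max = 5000,
                                rel.tol = 1e-12), control)
  if (!model$two_level) {
    fit <- fit_one_level(model, data, ctl)
  } else if (identical(model$between, "saturated")) {
    fit <- fit_profiled_max(model, data, ctl)
  } else {
    fit <- fit_joint(model, data, ctl)
  }
  th <- fit$estimates[fit$map$mat == "theta"]
  if (any(th < 0)) {
    fit$heywood <- names(th)[th < 0]
    warning("Heywood case: negative residual variance for ",
            paste(fit$heywood, collapse = ", "), call. = FALSE)
  }
  if (se) fit <- standard_errors(fit)
  fit
}

as_one_level_data <- function(data) {
  if (inherits(data, "mlcfa_decomp"))
    list(S = data$S_T, N = data$N)
  else if (is.list(data) && all(c("S", "N") %in% names(data)))
    list(S = as.matrix(data$S), N = data$N)
  else stop("one-level models need a decomposition or list(S, N)",
            call. = FALSE)
}

run_nlminb <- function(obj, start, ctl) {
  grad <- function(x) num_gradient(obj, x)
  res <- stats::nlminb(start, obj, gradient = grad,
                       control = list(iter.max = ctl$iter.max,
                                      eval.max = ctl$eval.max,
                                      rel.tol = ctl$rel.tol))
  par <- res$par; fval <- res$objective
  g <- grad(par)
  # Newton polish: nlminb stops on relative-F change, which can leave the
  # gradient just above tolerance near a flat optimum
  for (k in 1:3) {
    if (!is.finite(max(abs(g))) || max(abs(g)) < 1e-8) break
    H <- tryCatch(num_hessian(obj, par), error = function(e) NULL)
    if (is.null(H)) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    fc <- obj(cand)
    if (!is.finite(fc) || fc > fval + 1e-12) break
    par <- cand; fval <- fc; g <- grad(par)
  }
  gn <- max(abs(g))
  list(par = par, objective = fval,
       n_iter = res$iterations,
       converged = is.finite(gn) && gn < 1e-6,
       gradient_norm = gn)
}

fit_one_level <- function(model, data, ctl) {
  d <- as_one_level_data(data)
  S <- d$S; N <- d$N; p <- nrow(S)
  map <- param_map(model)
  logdetS <- as.numeric(determinant(S)$modulus)
  build <- function(x) level_sigma(model$within, x, map, p)$Sigma
  obj <- function(x) {
    v <- f_ml_quiet(S, build(x), logdetS, p)
    if (is.na(v)) 1e10 else v
  }
  start <- start_values_level(model$within, map, diag(S), S)
  res <- run_nlminb(obj, start, ctl)
  est <- stats::setNames(res$par, map$label)
  lev <- level_sigma(model$within, res$par, map, p)
  new_fit(model, map, est, F_min = res$objective, res = res,
          N = N, G = NA_integer_, c = NA_real_,
          implied = list(implied_total = lev$Sigma),
          params = list(within = level_as_params(lev)),
          obj_weighted = function(x) (N - 1) * obj(x),
          data_used = list(S_T = S, N = N))
}

# saturated between: profile objective is (N - G) * f_ml(S_PW, Sigma_W)
fit_profiled_max <- function(model, data, ctl) {
  stopifnot(inherits(data, "mlcfa_decomp"))
  p <- data$p
  map <- param_map(model)
  w <- map$level == "within"
  map_w <- map[w, , drop = FALSE]
  logdetW <- as.numeric(determinant(data$S_PW)$modulus)
  build_w <- function(x) level_sigma(model$within, x, map_w, p)$Sigma
  obj_w <- function(x) {
    v <- f_ml_quiet(data$S_PW, build_w(x), logdetW, p)
    if (is.na(v)) 1e10 else v
  }
  start <- start_values_level(model$within, map_w, diag(data$S_PW),
                              data$S_PW)
  res <- run_nlminb(obj_w, start, ctl)
  lev_w <- level_sigma(model$within, res$par, map_w, p)
  Sigma_B <- (data$S_B - lev_w$Sigma) / data$c
  F_min <- f_muml(data, lev_w$Sigma, Sigma_B)

  map_b <- map[!w, , drop = FALSE]
  est <- stats::setNames(
    c(res$par, Sigma_B[cbind(map_b$i, map_b$j)]),
    c(map_w$label, map_b$label))
  fit <- new_fit(model, map, est, F_min = F_min, res = res,
                 N = data$N, G = data$G, c = data$c,
                 implied = list(implied_within = lev_w$Sigma,
                                implied_between = Sigma_B),
                 params = list(within = level_as_params(lev_w),
                               between = NULL),
                 obj_weighted = function(x)
                   (data$N - data$G) * obj_w(x),
                 data_used = data)
  fit$profiled <- TRUE
  fit
}

fit_joint <- function(model, data, ctl) {
  stopifnot(inherits(data, "mlcfa_decomp"))
  p <- data$p; N <- data$N; G <- data$G; cc <- data$c
  map <- param_map(model)
  w <- map$level == "within"
  logdetW <- as.numeric(determinant(data$S_PW)$modulus)
  logdetB <- as.numeric(determinant(data$S_B)$modulus)
  build <- function(x) {
    list(W = level_sigma(model$within, x[w], map[w, , drop = FALSE], p),
         B = level_sigma(model$between, x[!w], map[!w, , drop = FALSE], p))
  }
  obj_total <- function(x) {
    lv <- build(x)
    fw <- f_ml_quiet(data$S_PW, lv$W$Sigma, logdetW, p)
    if (is.na(fw)) return(1e10)
    fb <- f_ml_quiet(data$S_B, lv$W$Sigma + cc * lv$B$Sigma, logdetB, p)
    if (is.na(fb)) return(1e10)
    G * fb + (N - G) * fw
  }
  obj <- function(x) obj_total(x) / N   # per-observation scale
  s2b <- pmax((diag(data$S_B) - diag(data$S_PW)) / cc, 0.05)
  SB0 <- (data$S_B - data$S_PW) / cc
  start <- c(start_values_level(model$within, map[w, , drop = FALSE],
                                diag(data$S_PW), data$S_PW),
             start_values_level(model$between, map[!w, , drop = FALSE],
                                s2b, SB0))
  # a saturated within level starts at S_PW; make sure the between start
  # keeps the between bracket well defined
  res <- run_nlminb(obj, start, ctl)
  lv <- build(res$par)
  est <- stats::setNames(res$par, map$label)
  new_fit(model, map, est, F_min = obj_total(res$par), res = res,
          N = N, G = G, c = cc,
          implied = list(implied_within = lv$W$Sigma,
                         implied_between = lv$B$Sigma),
          params = list(within = level_as_params(lv$W),
                        between = level_as_params(lv$B)),
          obj_weighted = obj_total,
          data_used = data)
}

level_as_params <- function(lev) {
  if (is.null(lev$Lambda)) return(NULL)
  level_params(lev$Lambda, lev$Psi, lev$Theta)
}

new_fit <- function(model, map, est, F_min, res, N, G, c, implied,
                    params, obj_weighted, data_used) {
  out <- c(list(model = model, map = map, estimates = est,
                se = rep(NA_real_, length(est)),
                F_min = F_min, converged = res$converged,
                n_iter = res$n_iter, gradient_norm = res$gradient_norm,
                N = N, G = G, c = c,
                params = params,
                obj_weighted = obj_weighted,
                data_used = data_used),
           implied)
  names(out$se) <- names(est)
  class(out) <- "mlcfa_fit"
  out
}

#' Standard errors from the numerical Hessian
#'
#' `SE = sqrt(diag(2 H^-1))` where `H` is the central-difference Hessian
#' of the count-weighted discrepancy at the optimum (for one-level models
#' `(N - 1) F_ML`; for two-level models the MUML discrepancy). A singular
#' or indefinite Hessian leaves the SEs `NA` and records the condition
#' number in `fit$se_condition`. For profiled maximum-model fits, SEs are
#' available for the structured (within) parameters; the saturated
#' between-level elements are reported without SEs.
#'
#' @param fit a `mlcfa_fit`.
#' @return The fit with its `se` vector filled in.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "mlcfa_fit"))
  free <- if (isTRUE(fit$profiled)) fit$map$level == "within"
          else rep(TRUE, nrow(fit$map))
  x <- unname(fit$estimates[free])
  H <- num_hessian(fit$obj_weighted, x)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning("Hessian not positive definite at the optimum; ",
            "standard errors unavailable (condition number ",
            format(max(abs(ev)) / max(min(abs(ev)), 1e-300),
                   digits = 3), ")", call. = FALSE)
    fit$se_condition <- max(abs(ev)) / max(min(abs(ev)), 1e-300)
    return(fit)
  }
  fit$se[free] <- sqrt(diag(2 * solve(H)))
  fit$se_condition <- max(ev) / min(ev)
  fit
}

#' @export
print.mlcfa_fit <- function(x, digits = 3, ...) {
  cat("Fit [", x$model$kind, "]: F_min = ",
      format(x$F_min, digits = 6),
      if (x$converged) ", converged" else ", NOT converged",
      " (", x$n_iter, " iterations, |grad| = ",
      format(x$gradient_norm, digits = 3), ")\n", sep = "")
  tab <- data.frame(estimate = round(x$estimates, digits),
                    se = round(x$se, digits))
  print(tab)
  invisible(x)
}
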