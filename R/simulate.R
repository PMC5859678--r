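#' Define a two-level normal factor population
#'
#' A data-generating population for clustered indicator data:
#' `y_gi = mu + Lambda_B eta_g + eps_g + Lambda_W eta_gi + eps_gi` with
#' independent normal cluster factors `eta_g ~ N(0, Psi_B)`, cluster
#' residuals `eps_g ~ N(0, Theta_B)`, case factors `eta_gi ~ N(0, Psi_W)`
#' and case residuals `eps_gi ~ N(0, Theta_W)`.
#'
#' @param within,between [level_params()] objects sharing the indicator
#'   dimension p (row names of the within `Lambda` supply indicator
#'   labels).
#' @param G number of clusters (>= 2).
#' @param n cluster size: a scalar for a balanced design or a length-G
#'   vector of sizes.
#' @param mu grand-mean vector (default 0).
#' @param labels indicator labels (default from `within`, else
#'   `V1..Vp`).
#' @return An object of class `two_level_population`.
#' @export
two_level_population <- function(within, between, G, n, mu = 0,
                                 labels = NULL) {
  stopifnot(inherits(within, "level_params"),
            inherits(between, "level_params"))
  p <- nrow(within$Lambda)
  if (nrow(between$Lambda) != p)
    stop("within and between must share the indicator dimension",
         call. = FALSE)
  if (G < 2) stop("G must be >= 2", call. = FALSE)
  n_g <- if (length(n) == 1) rep(as.integer(n), G) else as.integer(n)
  if (length(n_g) != G || any(n_g < 1))
    stop("'n' must be a scalar or length-G vector of sizes >= 1",
         call. = FALSE)
  if (is.null(labels))
    labels <- rownames(within$Lambda)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  mu <- rep_len(mu, p)
  for (ps in list(within$Psi, between$Psi))
    if (min(eigen(ps, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("factor covariance matrices must be positive definite",
           call. = FALSE)
  structure(list(within = within, between = between, G = G, n_g = n_g,
                 mu = mu, p = p, labels = labels),
            class = "two_level_population")
}

#' Population moments and intraclass correlations
#'
#' @param pop a [two_level_population()].
#' @return list with `Sigma_W`, `Sigma_B` (per-level implied covariance
#'   matrices) and `icc_pop` (per-indicator
#'   `Sigma_B_jj / (Sigma_B_jj + Sigma_W_jj)`).
#' @export
population_moments <- function(pop) {
  stopifnot(inherits(pop, "two_level_population"))
  SW <- implied_covariance(pop$within)
  SB <- implied_covariance(pop$between)
  dimnames(SW) <- dimnames(SB) <- list(pop$labels, pop$labels)
  list(Sigma_W = SW, Sigma_B = SB,
       icc_pop = stats::setNames(diag(SB) / (diag(SB) + diag(SW)),
                                 pop$labels))
}

# PSD-tolerant multivariate normal draw (eigenvalue square root)
rmvn_psd <- function(n, Sigma) {
  p <- nrow(Sigma)
  if (max(abs(Sigma)) == 0) return(matrix(0, n, p))
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  matrix(stats::rnorm(n * p), n, p) %*% (t(e$vectors) * sqrt(ev))
}

#' Generate a clustered dataset from a two-level population
#'
#' Deterministic given the seed. Cluster and case labels are zero-padded
#' so that the dataset's string ordering matches the generation order.
#'
#' @param pop a [two_level_population()].
#' @param seed integer seed for all random draws.
#' @return a [multilevel_dataset()].
#' @export
generate_dataset <- function(pop, seed) {
  stopifnot(inherits(pop, "two_level_population"))
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required for reproducible generation",
         call. = FALSE)
  set.seed(as.integer(seed))
  G <- pop$G; n_g <- pop$n_g; p <- pop$p
  eta_b <- rmvn_psd(G, pop$between$Psi) %*% t(pop$between$Lambda)
  eps_b <- rmvn_psd(G, as.matrix(pop$between$Theta))
  cl_part <- eta_b + eps_b
  N <- sum(n_g)
  eta_w <- rmvn_psd(N, pop$within$Psi) %*% t(pop$within$Lambda)
  eps_w <- rmvn_psd(N, as.matrix(pop$within$Theta))
  g_idx <- rep(seq_len(G), n_g)
  y <- sweep(cl_part[g_idx, , drop = FALSE] + eta_w + eps_w, 2, pop$mu,
             `+`)
  colnames(y) <- pop$labels
  cl <- sprintf(paste0("g%0", nchar(G), "d"), g_idx)
  multilevel_dataset(y, cluster_id = cl)
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Fits a model to `reps` independent datasets drawn from a population
#' and aggregates estimates, empirical standard errors (SD of estimates
#' across replications), mean reported standard errors, and (optionally)
#' bias against supplied true values, together with the mean chi-square
#' statistic at the model's reporting scope. Replications that fail to
#' converge are excluded and counted.
#'
#' @param pop a [two_level_population()].
#' @param model a `mlcfa_model` to fit to every replication.
#' @param reps number of replications (>= 2).
#' @param seed integer master seed; replication r uses `seed + r`.
#' @param true optional named vector of true parameter values (names
#'   matching the fit's parameter labels) for the bias column.
#' @return list with `summary` (per-parameter data frame), `chi2`
#'   (mean/sd of the chi-square and its df), `n_converged`,
#'   `n_nonconverged`, `reps`, `seed`.
#' @export
recovery_experiment <- function(pop, model, reps, seed, true = NULL) {
  stopifnot(inherits(pop, "two_level_population"),
            inherits(model, "mlcfa_model"), reps >= 2)
  est <- se <- NULL
  chi2s <- dfs <- numeric(0)
  bad <- 0L
  for (r in seq_len(reps)) {
    ds <- generate_dataset(pop, seed = as.integer(seed) + r)
    dec <- compute_decomposition(ds)
    fit <- tryCatch(fit_model(model, dec), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { bad <- bad + 1L; next }
    cs <- chi_square(fit)
    chi2s <- c(chi2s, cs$chi2); dfs <- c(dfs, cs$df)
    est <- rbind(est, fit$estimates)
    se <- rbind(se, fit$se)
  }
  if (is.null(est))
    stop("no replication converged", call. = FALSE)
  mean_est <- colMeans(est)
  out <- data.frame(parameter = colnames(est),
                    mean_est = unname(mean_est),
                    emp_se = unname(apply(est, 2, stats::sd)),
                    mean_se = unname(colMeans(se)),
                    stringsAsFactors = FALSE)
  if (!is.null(true)) {
    tv <- true[out$parameter]
    out$true <- unname(tv)
    out$bias <- out$mean_est - unname(tv)
  }
  list(summary = out,
       chi2 = list(mean = mean(chi2s), sd = stats::sd(chi2s),
                   df = unique(dfs)),
       n_converged = nrow(est), n_nonconverged = bad,
       reps = reps, seed = seed)
}

#' Balanced benchmark population
#'
#' A balanced two-level population widely used as a validation design for
#' multilevel CFA estimators: p indicators with unit-variance factors,
#' all loadings 0.80 and residual variances 0.36 at both levels (so each
#' level contributes unit indicator variance and the population ICC is
#' 0.5), a single within-level factor, and three correlated between-level
#' factors (three indicators each, factor covariances 0.30), with 50
#' clusters of 200 cases each.
#'
#' @param G,n cluster count and size (defaults 50 and 200).
#' @return a [two_level_population()] with indicators `V1..V9`.
#' @export
benchmark_population <- function(G = 50, n = 200) {
  p <- 9
  lab <- paste0("V", 1:p)
  LW <- matrix(0.8, p, 1, dimnames = list(lab, "W_f1"))
  LB <- matrix(0, p, 3, dimnames = list(lab, c("B_f1", "B_f2", "B_f3")))
  LB[1:3, 1] <- LB[4:6, 2] <- LB[7:9, 3] <- 0.8
  PsiB <- matrix(0.30, 3, 3); diag(PsiB) <- 1
  two_level_population(
    within = level_params(LW, 1, rep(0.36, p)),
    between = level_params(LB, PsiB, rep(0.36, p)),
    G = G, n = n)
}
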