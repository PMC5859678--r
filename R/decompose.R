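#' MUML scaling constant
#'
#' The common-group-size scalar used by Muthen's limited-information
#' estimator to weight the between-level variance component:
#' `c = (N^2 - sum(n_g^2)) / (N * (G - 1))`. For a balanced design it
#' equals the common cluster size exactly; in general it is close to the
#' average cluster size and never exceeds the largest one.
#'
#' @param n_g vector of cluster sizes (length G >= 2).
#' @return The scalar `c`.
#' @examples
#' scaling_constant(rep(200, 50))  # balanced: exactly 200
#' scaling_constant(c(2, 4))       # 16/6
#' @export
scaling_constant <- function(n_g) {
  n_g <- as.numeric(n_g)
  G <- length(n_g)
  if (G < 2) stop("at least 2 clusters required", call. = FALSE)
  if (any(n_g < 1)) stop("cluster sizes must be >= 1", call. = FALSE)
  N <- sum(n_g)
  (N^2 - sum(n_g^2)) / (N * (G - 1))
}

#' Decompose the sample covariance of a clustered dataset
#'
#' Computes the three MUML ingredient matrices: the total covariance
#' `S_T`, the pooled within-cluster covariance `S_PW` (an unbiased
#' estimator of the within-level population covariance), and the
#' size-weighted scaled between covariance
#' `S_B = sum_g n_g (ybar_g - ybar)(ybar_g - ybar)' / (G - 1)`
#' (an unbiased estimator of `Sigma_W + c * Sigma_B`), together with the
#' scaling constant `c`. The matrices satisfy the exact additivity
#' identity `(N - 1) S_T = (N - G) S_PW + (G - 1) S_B`.
#'
#' Datasets flagged `pairwise` by [apply_missing_policy()] are decomposed
#' entrywise on pairwise-complete rows (the additivity identity is then
#' only approximate and the effective `N` is the minimum pairwise count);
#' datasets containing `NA` without a declared policy are rejected.
#'
#' @param ds a `mlcfa_data` object.
#' @return An object of class `mlcfa_decomp` with components `S_T`,
#'   `S_PW`, `S_B`, `c`, `N`, `G`, `n_g`, `p`, `grand_mean`,
#'   `group_means` and `labels`.
#' @examples
#' d <- multilevel_dataset(cbind(y = c(0, 2, 4, 6)), rep(1:2, each = 2))
#' compute_decomposition(d)$S_B  # 16
#' @export
compute_decomposition <- function(ds) {
  stopifnot(inherits(ds, "mlcfa_data"))
  if (anyNA(ds$values)) {
    if (identical(attr(ds, "na_policy"), "pairwise"))
      return(decompose_pairwise(ds))
    stop("dataset contains missing cells; apply_missing_policy() first",
         call. = FALSE)
  }
  N <- ds$N; G <- ds$G; p <- ds$p
  if (N <= G)
    stop("within covariance undefined: need N > G ",
         "(at least one cluster with 2 or more cases)", call. = FALSE)
  y <- ds$values
  n_g <- ds$n_g
  gm <- rowsum(y, ds$cluster_id) / as.vector(n_g)   # G x p group means
  ybar <- colMeans(y)

  ctr_t <- sweep(y, 2, ybar)
  S_T <- crossprod(ctr_t) / (N - 1)
  ctr_w <- y - gm[ds$cluster_id, , drop = FALSE]
  S_PW <- crossprod(ctr_w) / (N - G)
  dev_b <- sweep(gm, 2, ybar)
  S_B <- crossprod(dev_b * sqrt(as.vector(n_g))) / (G - 1)

  if (any(diag(S_T) <= 1e-14))
    stop("zero-variance indicator(s): ",
         paste(ds$labels[diag(S_T) <= 1e-14], collapse = ", "),
         call. = FALSE)
  dimnames(S_T) <- dimnames(S_PW) <- dimnames(S_B) <-
    list(ds$labels, ds$labels)
  structure(list(S_T = S_T, S_PW = S_PW, S_B = S_B,
                 c = scaling_constant(n_g),
                 N = N, G = G, n_g = n_g, p = p,
                 grand_mean = ybar, group_means = gm,
                 labels = ds$labels),
            class = "mlcfa_decomp")
}

# Pairwise-complete decomposition: every (j, k) entry of every matrix uses
# the rows on which both indicators are observed; means are recomputed on
# the same rows, so single matrices are valid covariances but joint PSD is
# not guaranteed (the engine's positive-definiteness check catches that).
decompose_pairwise <- function(ds) {
  y <- ds$values
  p <- ds$p
  cl <- ds$cluster_id
  pn <- attr(ds, "pairwise_n")
  S_T <- S_PW <- S_B <- matrix(NA_real_, p, p,
                               dimnames = list(ds$labels, ds$labels))
  N_eff <- G_eff <- Inf
  for (j in seq_len(p)) for (k in j:p) {
    ok <- !is.na(y[, j]) & !is.na(y[, k])
    yj <- y[ok, j]; yk <- y[ok, k]; cg <- cl[ok]
    n_g <- table(cg)
    Njk <- length(yj); Gjk <- length(n_g)
    if (Njk < 3 || Gjk < 2 || Njk <= Gjk)
      stop(sprintf(
        "too few pairwise-complete cases for (%s, %s)",
        ds$labels[j], ds$labels[k]), call. = FALSE)
    mj <- mean(yj); mk <- mean(yk)
    gmj <- rowsum(yj, cg) / as.vector(n_g)
    gmk <- rowsum(yk, cg) / as.vector(n_g)
    S_T[j, k] <- S_T[k, j] <- sum((yj - mj) * (yk - mk)) / (Njk - 1)
    S_PW[j, k] <- S_PW[k, j] <-
      sum((yj - gmj[cg, 1]) * (yk - gmk[cg, 1])) / (Njk - Gjk)
    S_B[j, k] <- S_B[k, j] <-
      sum(as.vector(n_g) * (gmj - mj) * (gmk - mk)) / (Gjk - 1)
    N_eff <- min(N_eff, Njk); G_eff <- min(G_eff, Gjk)
  }
  if (any(diag(S_T) <= 1e-14))
    stop("zero-variance indicator(s): ",
         paste(ds$labels[diag(S_T) <= 1e-14], collapse = ", "),
         call. = FALSE)
  # cluster sizes from rows with at least one observed indicator
  keep <- rowSums(!is.na(y)) > 0
  n_g <- table(cl[keep])
  structure(list(S_T = S_T, S_PW = S_PW, S_B = S_B,
                 c = scaling_constant(n_g),
                 N = N_eff, G = min(G_eff, length(n_g)), n_g = c(n_g),
                 p = p,
                 grand_mean = colMeans(y, na.rm = TRUE),
                 group_means = NULL, labels = ds$labels,
                 pairwise = TRUE, pairwise_n = pn),
            class = "mlcfa_decomp")
}

#' Per-indicator intraclass correlations
#'
#' Method-of-moments ICC from the MUML decomposition: the between variance
#' of indicator j is estimated as `(S_B[j,j] - S_PW[j,j]) / c`, truncated
#' at zero (a negative raw estimate yields ICC 0 with a warning and is
#' retained in the `sigma2_b_raw` column), and
#' `icc_j = sigma2_b / (sigma2_b + sigma2_w)`. Non-trivial ICCs signal
#' between-cluster variation and hence the need for multilevel modeling.
#'
#' @param decomp a `mlcfa_decomp` object.
#' @return A data frame of class `mlcfa_icc` with columns `indicator`,
#'   `sigma2_b`, `sigma2_w`, `icc` and `sigma2_b_raw`.
#' @export
icc_table <- function(decomp) {
  stopifnot(inherits(decomp, "mlcfa_decomp"))
  raw <- (diag(decomp$S_B) - diag(decomp$S_PW)) / decomp$c
  if (any(raw < 0))
    warning("negative raw between-variance estimate truncated to 0 for: ",
            paste(decomp$labels[raw < 0], collapse = ", "), call. = FALSE)
  s2b <- pmax(raw, 0)
  s2w <- diag(decomp$S_PW)
  out <- data.frame(indicator = decomp$labels,
                    sigma2_b = unname(s2b), sigma2_w = unname(s2w),
                    icc = unname(s2b / (s2b + s2w)),
                    sigma2_b_raw = unname(raw),
                    stringsAsFactors = FALSE)
  class(out) <- c("mlcfa_icc", "data.frame")
  out
}

#' @export
print.mlcfa_decomp <- function(x, digits = 3, ...) {
  cat("MUML covariance decomposition: N =", x$N, ", G =", x$G,
      ", c =", format(x$c, digits = 6), "\n")
  cat("S_PW (pooled within):\n")
  print(round(x$S_PW, digits))
  cat("S_B (scaled between):\n")
  print(round(x$S_B, digits))
  invisible(x)
}
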