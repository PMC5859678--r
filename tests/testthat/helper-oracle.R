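# Independent weighted two-group ML oracle.
#
# Deliberately coded apart from the package engine: matrices are
# assembled by explicit loops, determinants/inverses use det()/solve()
# rather than Cholesky factors, and optimization uses optim(BFGS). It
# fits a two-level model with single-factor patterns at both levels
# (marker = first indicator) by treating the scaled-between and
# pooled-within matrices as two weighted ML "groups".

oracle_build_sigma <- function(lam_free, psi, th, p, marker) {
  lam <- c(marker, lam_free)
  S <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) {
    S[i, j] <- lam[i] * psi * lam[j]
    if (i == j) S[i, j] <- S[i, j] + th[i]
  }
  S
}

oracle_fml <- function(S, Sig) {
  p <- nrow(S)
  ev <- eigen((Sig + t(Sig)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev) || min(ev) <= 0) return(NA_real_)
  log(det(Sig)) + sum(diag(solve(Sig) %*% S)) - log(det(S)) - p
}

# parameter vector layout matches the free-parameter definition (free
# loadings, factor variance, residual variances; within then between)
oracle_fit_mcfa <- function(dec, marker_w = 1, marker_b = 1) {
  p <- dec$p
  nfree <- p - 1
  obj <- function(x) {
    lw <- x[1:nfree];            pw <- x[nfree + 1]
    tw <- x[(nfree + 2):(nfree + 1 + p)]
    off <- nfree + 1 + p
    lb <- x[(off + 1):(off + nfree)]; pb <- x[off + nfree + 1]
    tb <- x[(off + nfree + 2):(off + nfree + 1 + p)]
    SW <- oracle_build_sigma(lw, pw, tw, p, marker_w)
    SB <- oracle_build_sigma(lb, pb, tb, p, marker_b)
    fw <- oracle_fml(dec$S_PW, SW)
    fb <- oracle_fml(dec$S_B, SW + dec$c * SB)
    if (is.na(fw) || is.na(fb)) return(1e10)
    dec$G * fb + (dec$N - dec$G) * fw
  }
  start <- c(rep(0.7, nfree), 0.5 * dec$S_PW[1, 1], 0.5 * diag(dec$S_PW),
             rep(0.7, nfree),
             max((dec$S_B[1, 1] - dec$S_PW[1, 1]) / dec$c, 0.05) / 2,
             0.5 * pmax((diag(dec$S_B) - diag(dec$S_PW)) / dec$c, 0.05))
  res <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  res <- stats::optim(res$par, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  list(par = res$par, value = obj(res$par), obj = obj)
}
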