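---
title: "Multilevel CFA for clustered data: models, estimator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel CFA for clustered data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcfa)
```

## The problem

Survey data collected under cluster or multistage sampling — pupils in
schools, children in families, employees in firms — violate the
independence assumption of ordinary confirmatory factor analysis.
Responses within a cluster share cluster-level variance, so a one-level
CFA fitted to the total covariance matrix conflates two distinct
structures: the within-cluster covariance $\Sigma_W$ among individual
deviations, and the between-cluster covariance $\Sigma_B$ among cluster
means. The conflation biases loadings, inflates factor variances (they
absorb both components), and distorts standard errors and fit
statistics.

Multilevel CFA (MCFA) models the two components separately. This package
implements the covariance-decomposition route: Muthén's
limited-information maximum likelihood (MUML), which requires only three
sample matrices and works with any weighted two-group ML machinery.

## Decomposition and the MUML discrepancy

For $N$ cases in $G$ clusters of sizes $n_g$, with grand mean $\bar y$
and cluster means $\bar y_g$:

$$
S_T = \frac{1}{N-1}\sum_{g,i}(y_{gi}-\bar y)(y_{gi}-\bar y)', \qquad
S_{PW} = \frac{1}{N-G}\sum_{g,i}(y_{gi}-\bar y_g)(y_{gi}-\bar y_g)',
$$
$$
S_B = \frac{1}{G-1}\sum_g n_g(\bar y_g-\bar y)(\bar y_g-\bar y)', \qquad
c = \frac{N^2-\sum_g n_g^2}{N(G-1)}.
$$

These satisfy the exact identity
$(N-1)S_T = (N-G)S_{PW} + (G-1)S_B$, and under the two-level normal
model $E[S_{PW}] = \Sigma_W$ and $E[S_B] = \Sigma_W + c\,\Sigma_B$. Note
the $n_g$ weight in $S_B$: the unweighted cluster-mean covariance
satisfies neither the additivity identity nor the estimand above, so the
size-weighted (Muthén) form is the one implemented. For a balanced
design $c$ equals the common cluster size exactly; in general it is
close to the average size and never larger than the largest cluster.

The MUML discrepancy treats the two matrices as weighted ML "groups":

$$
F_{MUML} = G\left\{\ln|\Sigma_W + c\Sigma_B| +
\mathrm{tr}\big[(\Sigma_W + c\Sigma_B)^{-1}S_B\big] - \ln|S_B| -
p\right\} + (N-G)\left\{\ln|\Sigma_W| +
\mathrm{tr}\big[\Sigma_W^{-1}S_{PW}\big] - \ln|S_{PW}| - p\right\}.
$$

Its minimum is the model chi-square. For balanced designs MUML coincides
with full ML on the two-part likelihood; for unbalanced designs it is a
quasi-likelihood that replaces the varying $n_g$ by the single scalar
$c$ — the price paid for needing only two matrices.

ICC screening precedes modeling: with
$\hat\sigma^2_{B,j} = \max\{(S_{B,jj}-S_{PW,jj})/c,\,0\}$, the
intraclass correlation
$\hat\sigma^2_{B,j}/(\hat\sigma^2_{B,j}+S_{PW,jj})$ estimates the
between-cluster share of indicator $j$'s variance. The workflow's
advisory threshold defaults to 0.05 (configurable); below it, multilevel
modeling is typically not worth the extra parameters.

## The five model kinds and level-specific fit

Each level follows the factor-analytic structure
$\Sigma = \Lambda\Psi\Lambda' + \Theta$ with one loading per factor
fixed (the marker, default 1.0, user-settable — reference analyses that
fix markers at the population loading 0.8 are reproducible by setting
`marker_value = 0.8`). The kinds:

* **cfa** — one level, fitted to $S_T$ with Wishart weight $N-1$.
* **mcfa** — structured within and between levels under $F_{MUML}$.
* **max_mcfa** — the *maximum* model: structured within, saturated
  between. The saturated between level consumes exactly its own
  $p(p+1)/2$ moments, so its df equals the one-level CFA df and only
  within-level misfit contributes to the discrepancy.
* **ps_between** — the mirror image: saturated within, structured
  between; isolates between-level misfit.
* **saturated / independence** — reference models (exact fit with df 0;
  diagonal covariance baseline for CFI).

The three-step procedure: (1) fit the CFA and the maximum model and
compare their within-level estimates — incongruence (the workflow flags
any relative difference over 10% or any Wald-type contrast with
$|t|>1.96$) signals between-level structure; (2) settle the within model
using the maximum model's level-specific fit; (3) build the between
model with MCFA, judged by between-specific fit.

A deliberate reporting convention: the tabulated "MCFA" row shows
**between-specific** statistics (the statistics of the partially
saturated model sharing its between structure), not the overall
two-level chi-square. The df arithmetic of the reference analyses —
between-specific dfs of 9 and 24 where the overall two-level dfs would
be 16 and 33 — identifies this as the convention used by the original
tabulations, and it is also the natural companion to step 3, where the
within model has already been screened. `fit_statistics()` exposes all
scopes explicitly; `degrees_of_freedom()` is data-free, so every df is
checkable before any fitting.

## Fit indices: conventions where several exist

* **Chi-square.** Two-level: $F_{\min}$ itself (the weights are inside
  $F_{MUML}$). One-level: $(N-1)F_{\min}$ (Wishart convention, matching
  LISREL-style output).
* **CFI** $= 1 - \max(\chi^2-df,0)/\max(\chi^2_b-df_b,\ \chi^2-df,\ 0)$
  against an independence baseline *of the same scope* (for the between
  scope: saturated within, diagonal between). The baseline definition is
  this package's construction — reference tabulations never state
  theirs — so CFI values are documented as depending on it.
* **RMSEA** $= \sqrt{\max(\chi^2-df,0)/(df\,(N-1))}$ with $N$ the
  **total** number of cases in every scope. This reproduces the
  reference between-scope value (0.058 at $\chi^2=824.5$, $df=24$,
  $N=10{,}000$); using $G$ instead would give 0.825-scale values and is
  rejected.
* **SRMR** standardizes residuals by the sample-matrix diagonals; the
  within scope compares $S_{PW}$ with $\hat\Sigma_W$, the between scope
  compares $S_B$ with $\hat\Sigma_W + c\hat\Sigma_B$ (standardized by
  the $S_B$ diagonal — again a convention, stated because the
  between-scope recipe is not standardized in the literature).
* **$R^2_j$** $= (\Lambda\Psi\Lambda')_{jj} /
  [(\Lambda\Psi\Lambda')_{jj} + \Theta_{jj}]$ per level.

Congruence diagnostics follow the conventions that reproduce the
reference ranges: the relative difference divides by the **CFA**
estimate, $100(\hat\lambda_{CFA}-\hat\lambda_{ref})/\hat\lambda_{CFA}$
(the usual "relative bias" divides by the reference; only the CFA
denominator reproduces both the published minimum and maximum
simultaneously), and the Wald-type contrast uses
$t=(\hat\lambda_1-\hat\lambda_2)/\sqrt{SE_1^2+SE_2^2}$ with
$df = n_1+n_2-2$, treating the two fits as independent samples even
though they share the data — forced by the published dfs, and therefore
reported as a descriptive index, not a formal test. No family-wise
correction is applied; the count of $|t|>1.96$ contrasts is reported
instead.

## Numerical choices

* **Optimizer.** `nlminb` (quasi-Newton) over the free parameters with
  central-difference gradients (step $10^{-5}\max(1,|\theta|)$),
  followed by up to three guarded Newton polish steps using the
  numerical Hessian — `nlminb` stops on relative-F change, which can
  leave the gradient marginally above tolerance near flat optima.
  Convergence is declared when the gradient of the *per-observation*
  discrepancy (one-level: $F_{ML}$; two-level: $F_{MUML}/N$) falls below
  $10^{-6}$; this makes the criterion comparable across sample sizes.
* **Saturated between levels are profiled out.** For any $\Sigma_W$ the
  between bracket of $F_{MUML}$ is zeroed exactly by
  $\Sigma_B = (S_B-\Sigma_W)/c$, so maximum-model fits iterate only the
  within parameters against $(N-G)\,F_{ML}(S_{PW},\Sigma_W)$. The
  profile curvature equals the Schur complement of the joint Hessian,
  so within-parameter standard errors are identical to joint-fit ones;
  the saturated between elements are reported without SEs. This also
  makes the within-specific statistics *identically* equal to a
  one-level fit of the within model to $S_{PW}$ with weight $N-G$,
  which the tests verify.
* **Start values.** Markers at their fixed value; free loadings 0.7;
  factor variances at half the mean sample variance of their
  indicators (within level from $S_{PW}$, between from
  $\max\{(S_{B,jj}-S_{PW,jj})/c, 0.05\}$); factor covariances 0;
  residual variances at half the sample variances; saturated levels
  start at their exact-fit solutions. Scale-aware and deterministic.
* **No bounds.** Optimization is unconstrained; inadmissible solutions
  (negative residual variances — Heywood cases — or non-PD $\Psi$) are
  reported as warnings rather than clamped, mirroring classical SEM
  software so that the diagnostic information survives. Non-PD implied
  matrices during search are handled by a large penalty value.
* **Standard errors** are $\sqrt{\mathrm{diag}(2H^{-1})}$ with $H$ the
  central-difference Hessian (step $10^{-4}\max(1,|\theta|)$) of the
  count-weighted discrepancy at the optimum — the normal-theory
  quasi-likelihood information, with no sandwich correction. A singular
  or indefinite $H$ leaves SEs `NA` with a condition-number diagnostic.
* **p-values** use the central chi-square; no scaled/robust variants.
* **Missing data.** Listwise deletion is the default. Pairwise deletion
  (the behavior of the classical decomposition tools) is an explicit
  option: each matrix entry uses pairwise-complete rows, and the
  effective $N$ carried into likelihoods is the *minimum* pairwise
  count — a conservative documented choice, since no standard exists.
  Pairwise matrices need not be positive semidefinite; if one is not,
  the fit aborts with the offending eigenvalue rather than proceeding.
* **Identifiers** are opaque strings (`"01"` and `"1"` are different
  clusters); rows sort ascending by cluster then case label.

## What the generator emulates — and what it does not

`generate_dataset()` draws exactly the model the estimator assumes:
multivariate normal factors and residuals at both levels, independent
across levels and units, constant loadings across clusters.
`benchmark_population()` bundles the balanced validation design used
throughout the tests: nine indicators, one within factor and three
correlated between factors (three indicators each), all loadings 0.80,
all residual variances 0.36, between-factor covariances 0.30, 50
clusters of 200 — giving unit indicator variance at each level and
population ICC 0.5 for every indicator. The reference simulation this
mirrors additionally placed cross-loadings in its between-level true
model (specified only in an external source), so between-level point
estimates from that analysis are not regeneration targets here; the
bundled population uses simple structure at both levels, and only
within-level quantities and qualitative between-level patterns are
compared.

Passing recovery tests on these data therefore show that the estimator
and its standard errors are correct *under the assumed model*. They say
nothing about robustness to non-normality, categorical indicators,
informative cluster sizes, cluster-varying loadings, or missing-data
mechanisms — all outside the generator, and the first three outside
MUML's assumptions altogether.

Validation problem sizes are chosen to exercise the asymptotics that
matter while staying quick to rerun: unbiasedness of the decomposition
uses 300 replications of a 20-cluster design; chi-square calibration
uses 400 replications of a 40-cluster design (rejection rate at
$\alpha=0.05$ within three Monte-Carlo SEs); parameter recovery uses 100
replications of the full 50 × 200 benchmark, where the mean reported
loading SE reproduces the tabulated 0.009.

## Known limitations

* MUML is limited-information: for strongly unbalanced designs it is an
  approximation to full ML, and no raw-data FIML is provided for
  incomplete data (preprocess by imputation instead).
* Covariance structures only — no mean/intercept structure, no equality
  constraints, no multiple-group analysis, no categorical estimators,
  no robust corrections.
* The between level is estimated from $G$ cluster means; with small $G$
  (or $G \le p$, where $S_B$ is singular and the MUML between bracket
  undefined) between-level parameters are weakly identified and Heywood
  warnings are common — the diagnostics are the feature, not the bug.
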