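---
title: "Approximate likelihoods for generalized linear latent variable models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate likelihoods for generalized linear latent variable models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gllvmlite)
```

## The model

Multivariate abundance data record responses $y_{ij}$ (counts,
presence/absence, biomass) for $m$ species at $n$ sites.  A generalized
linear latent variable model (GLLVM) couples one GLM per species through a
small number $d \ll m$ of shared, site-level latent variables:

$$ g(\mu_{ij}) = \eta_{ij} = \alpha_i + \beta_{0j} + x_i'\beta_j +
   u_i'\gamma_j, \qquad u_i \sim N_d(0, I_d), $$

optionally with a random site intercept $\alpha_i \sim N(0, \sigma^2)$
(written jointly as $u^*_i = (\alpha_i, u_i')'$ with implicit loading 1 and
prior covariance $C = \mathrm{bdiag}(\sigma^2, I_d)$).  The term
$u_i'\gamma_j$ induces a rank-$d$ residual correlation across species; with
$d = 2$ the predicted $u_i$ double as a model-based ordination.  Conditional
on $u^*_i$ the responses are independent draws from the response family.
To fix rotation and scale, the loading matrix $\Gamma = (\gamma_1 \cdots
\gamma_m)'$ is constrained lower triangular with positive diagonal and the
latent variables are standard normal.

Supported families: Poisson (log link), negative binomial (log link,
$\mathrm{Var}(y) = \mu + \phi\mu^2$), Bernoulli (probit or logit), and a
gaussian/identity family.  The gaussian family exists for verification, not
analysis: both approximations below are *exact* for normal responses, which
yields closed-form oracles used throughout the test suite.

The marginal log-likelihood integrates the latent variables out,

$$ \ell(\Psi) = \sum_{i=1}^n \log \int \prod_{j=1}^m
   f(y_{ij} \mid u^*_i; \Psi)\, f(u^*_i; \sigma^2)\, du^*_i, $$

and has no closed form for non-normal responses.  The package maximizes two
closed-form approximations to it.

## The two engines

**Laplace approximation** (`fit_la`).  For each site the log-integrand
$g_i(u) = \sum_j \log f(y_{ij} \mid \eta_{ij}) - \tfrac12 u'C^{-1}u -
\tfrac12\log\det C - \tfrac{p}{2}\log 2\pi$ is maximized over $u$ by a
batched Newton method (analytic curvature, step halving, Levenberg damping),
and a second-order expansion around the mode $\hat u^*_i$ gives

$$ \tilde\ell(\Psi) = \sum_i \Big\{ g_i(\hat u^*_i) + \tfrac{p}{2}\log 2\pi
   - \tfrac12 \log\det G_i \Big\}, \qquad
   G_i = \sum_j w_{ij}\gamma^*_j\gamma^{*\prime}_j + C^{-1}, $$

with $w_{ij} = -\partial^2 \log f / \partial\eta^2$ evaluated at the mode.
A scaling of the exponent by $1/m$ is sometimes used to present this
expansion; it cancels in the final expression, so the implementation works
with the unscaled joint density.  Derived from first principles, the
curvature uses $C^{-1}$ (not $C$) and carries the same dispersion weighting
as the log-density itself; the implementation is verified against
finite-difference Hessians of $g_i$.  The $\hat u^*_i$ are the latent
predictions and $G_i^{-1}$ their prediction covariances.

**Variational approximation** (`fit_va`).  Positing independent normal
densities $q(u^*_i) = N(a_i, A_i)$ and applying Jensen's inequality yields
a strict lower bound

$$ \underline\ell(\Psi, \xi) = \sum_{ij} E_q\{\log f(y_{ij}\mid\eta_{ij})\}
   + \tfrac12 \sum_i \big\{ \log\det A_i - \mathrm{tr}(C^{-1}A_i)
   - a_i'C^{-1}a_i - \log\det C + p \big\}, $$

where under $q$ the predictor is univariate normal with mean
$\tilde\eta_{ij} = \beta_{0j} + x_i'\beta_j + a_i'\gamma^*_j$ and variance
$s^2_{ij} = \gamma^{*\prime}_j A_i \gamma^*_j$.  The bound is maximized
jointly over $(\Psi, \xi)$, treating the variational parameters as ordinary
parameters.  The means $a_i$ are the latent predictions and $A_i$ the
prediction covariances.

All data constants ($\log y!$, negative-binomial combinatorial terms, the
normal normalizing constants) are **included** in both objectives and in the
bound's $+p/2$ term, so the two engines and the brute-force quadrature
oracle (`marginal_loglik_quad`) are directly comparable on one scale, and
$\underline\ell \le \ell$ holds as an invariant that the tests check.

### Gaussian expectations

$E_q\{\log f\}$ has a closed form for the Poisson/log family
($y\tilde\eta - e^{\tilde\eta + s^2/2} - \log y!$) and for the gaussian
family.  For Bernoulli and negative-binomial responses the package computes
the one-dimensional Gaussian expectation by fixed 32-point Gauss–Hermite
quadrature (`expected_loglik_1d`).  This family-agnostic route preserves the
bound to quadrature accuracy, is verifiable against Monte Carlo, and avoids
family-specific reparameterizations; closed forms could be added later as an
optimization.  The gradient of the quadrature is taken through the nodes
($\partial/\partial s^2 = \sum_k w_k f'(\eta_k) z_k / 2s$), so objective and
gradient are *exactly* consistent for the optimizer; the $s^2 \to 0$ limit
uses $E[f'']/2$.

### Optimization

No automatic-differentiation backend is assumed: both engines ship fully
analytic gradients.  For the Laplace objective this includes the
implicit-function correction of the $\log\det G_i$ term through the inner
optimum ($d\hat u/d\theta = G^{-1}\, \partial^2 g/\partial u\,\partial
\theta$), which needs third derivatives of each family's log-density; every
gradient is tested against central finite differences.

Unconstrained parameterization: dispersions, variances and the loading
diagonal are optimized as $\log\phi_j$, $\log\sigma^2$, $\log\gamma_{jj}$;
only the lower triangle of $\Gamma$ is free; $A_i$ is parameterized by its
block-diagonal Cholesky factor (scalar row-effect block, unstructured
$d \times d$ block) with log diagonal.  Parameter floors
($\gamma_{jj} \ge 10^{-4}$, $\phi_j \ge 10^{-6}$, $\sigma^2 \ge 10^{-6}$,
variational variances $\ge 10^{-8}$) are enforced as box constraints.

The outer maximization uses `nlminb` followed, when needed, by bounded
quasi-Newton and conjugate-gradient polish rounds.  A fit is flagged
converged when the projected gradient max-norm falls below
`grad_tol` $\times \max(1, |\mathrm{objective}|/1000)$ — the scaling
reflects that below this level the attainable improvement $g^2/2H$ drops
under the objective's floating-point noise floor — or when the polish
rounds cannot improve the objective by more than $10^{-7}$ relative
(typical of boundary-degenerate optima, e.g. a dispersion at its floor).
Defaults: `maxit = 2000`, `rel_tol = 1e-12`, `grad_tol = 1e-4`,
`quad = 32`, initial variational spread $A_i = 0.1 I$ (small but
nondegenerate; the choice only affects the starting point).

## Starting values

The observed likelihood can be multimodal, and gradient methods inherit the
basin of their start.  Four strategies (`make_start`):

* **res** — fit a GLM per species (negative-binomial dispersions by maximum
  likelihood, degenerate columns fall back to clamped intercepts), form
  Dunn–Smyth randomized-quantile residuals
  $r_{ij} = \Phi^{-1}\{z_{ij}F_{ij}(y_{ij}) + (1-z_{ij})F^-_{ij}(y_{ij})\}$
  — exactly standard normal under a correct model — and run a $d$-factor
  analysis on them (maximum likelihood, regression scores, truncated-SVD
  fallback on Heywood cases).  GLM coefficients start the fixed effects,
  the rotated loadings/scores start $\Gamma$ and $U$; row effects start at
  zero.
* **res3** — `n_sets` (default 3) copies of `res` whose latent starts are
  jittered with $N(0, 0.2^2)$ noise; the multi-start fit keeps the highest
  final objective.
* **zero** — everything at zero except the loading diagonal at its floor
  and dispersions at one.
* **random** — latents drawn $N_d(0, I)$, then per-species GLMs on
  covariates plus drawn latents supply coefficients and loadings.

NB dispersion starts use the per-species GLM maximum-likelihood estimates
(fallback 1); the row-effect variance starts at 0.25.  One integer seed
drives residual jitter, latent draws and `res3` jitter, so starting values
are reproducible.

## Inference

Standard errors come from the observed information of the approximate
objective: for Laplace, the inverse negative Hessian of $\tilde\ell$ over
$\Psi$; for VA, the $\Psi$-block of the inverse negative Hessian of
$\underline\ell$ over $(\Psi, \xi)$, computed by a Schur complement (the
tests confirm it equals the corresponding block of the full inverse).
Hessians are finite differences of the analytic gradients.  Wald intervals
are formed on the estimation scale — $\log\phi$, $\log\sigma^2$ — which is
also the scale on which simulation summaries (bias, RMSE, coverage, CI
width) are reported for dispersions; loading diagonals are reported on the
natural scale by the delta method.  Singular Hessians fall back to a
pseudo-inverse (singular values below $10^{-10}$ of the maximum truncated)
with a flag.

## Simulation harness and metrics

`simulate_responses` draws $u_i \sim N_d(0, I)$, optionally $\alpha_i \sim
N(0, \sigma^2)$, and samples responses from the conditional family;
`generate_parameters` supplies constraint-valid synthetic "truths"
(defaults: intercepts uniform on $(-1, 1)$, loadings with spread 0.5,
NB dispersion 0.7, row-effect variance 0.25 — the row-effect value used in
the simulation designs; the rest chosen once as representative of moderate
abundance data).  `run_design` loops grid cells and replicates, fits the
requested engines, and aggregates bias/RMSE/coverage/CI width
(`summarize_cell`), latent and loading Procrustes errors, and variation
explained; per-replicate results are persisted as CSVs so interrupted runs
resume deterministically.

**Procrustes error** (`procrustes_error`) solves the full superposition
problem — rotation, translation, uniform scale — in closed form and
reports the per-entry RMS residual $\sqrt{SS/(nd)}$.  The exact
normalization used for published tables of this kind is not standardized,
so cross-study comparisons of its *values* should be treated as trend-level
only; the invariances (rotation/reflection/translation/positive scaling)
and a grid-search oracle pin the implementation down.

**Variation explained** (`variation_explained`) compares mean-scale
predictions against an intercept-only null,
$VE = 1 - \sum|\hat\mu - \mu| / \sum|\hat\mu_{null} - \mu|$, evaluated
against the true generating means; with simulated truths there is no need
for cross-validation folds.

`compare_starts` fits once per starting strategy and reports final
objectives relative to `res3` (negative = worse), the convention used for
starting-value comparisons.

## What the synthetic generator does and does not emulate

The generator reproduces the stated data-generating process exactly:
standard-normal latents, independent exponential-family responses, a
low-rank loading structure, optional normal row effects.  It does **not**
emulate features of real community data such as zero inflation beyond the
family's own, phylogenetic or spatial structure in the loadings, covariate
collinearity, or model misspecification.  A green recovery test therefore
establishes correctness of the estimation machinery *under the model*, not
robustness to violations of it.

## Numerical choices and degenerate inputs

* Tensor Gauss–Hermite quadrature (the test oracle) is limited to
  $d + \mathrm{row\_effect} \le 3$; it is exact only in the limit and
  noticeably inexact when the posterior is much narrower than the prior,
  which is why the gaussian exactness tests use the closed-form normal
  likelihood as reference instead.
* Dunn–Smyth arguments are clamped to $[10^{-10}, 1 - 10^{-10}]$ before
  $\Phi^{-1}$.
* Sites whose inner Newton step has a decrement below machine noise are
  frozen; a fit with such sites is only declared converged if their
  gradient is otherwise small.
* All-zero (or all-one) binary species columns fall back to intercepts at
  the $1/(2n)$ frequency floor and are flagged.
* Rank-deficient loading matrices are rejected in `constrain_loadings`;
  the factor-analysis fallback perturbs minimally instead of failing.

## Known limitations

* Ordinal, Tweedie and zero-inflated families, offsets, and fixed row
  effects are out of scope.
* No structured (low-rank or sparse) variational covariances; cost grows
  with $n \times d(d+1)/2$ variational parameters.
* Large-sample properties of variational estimators are not fully
  characterized in the literature; the Wald intervals here are calibrated
  empirically in the test suite, not backed by asymptotic theory.
* The Laplace engine is known to be biased for highly discrete responses
  (small counts, binary data at small $n$) — visible in this package as
  negative-binomial dispersions driven to their floor on small samples;
  such fits are flagged rather than hidden.
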