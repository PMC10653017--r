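---
title: "Prior adaptive semi-supervised estimation of phenotyping models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior adaptive semi-supervised estimation of phenotyping models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electronic-health-record (EHR) phenotyping asks for a classifier of a
patient's true disease status $Y \in \{0,1\}$ from curated EHR features
$X \in \mathbb{R}^p$ (log-transformed code counts, lab values, NLP mention
counts).  Gold-standard labels come from manual chart review and are
expensive: typically a few hundred labeled records sit inside a cohort of
tens of thousands.  Every record, labeled or not, carries a *surrogate*
$S$ — an automatically available proxy such as the billing-code count for
the target disease — that is predictive of $Y$ but imperfect.

`passr` implements estimators for the high-dimensional logistic phenotype
model

$$\operatorname{logit} \Pr(Y = 1 \mid S, X) = \zeta + \gamma S + X^\top\beta,$$

that exploit the large unlabeled set through $S$, together with the
supervised and semi-supervised benchmarks they are compared against, a
simulation engine, and evaluation metrics.

## The surrogate direction

Assume a single-index model for the surrogate: $S = f(X^\top\alpha,
\epsilon)$ with unknown link $f$ and noise independent of $X$.  Under an
elliptical-design condition (linear conditional expectations of
projections, satisfied e.g. by multivariate normal designs and
approximately by high-dimensional ones), the *direction* of $\alpha$ is
recovered by plain least squares of $S$ on $X$ — no knowledge of $f$ is
needed.  If additionally $X \perp\!\!\!\perp S \mid Y$ (the surrogate is a
noisy measurement of $Y$ that adds no feature information of its own —
the "prior" condition), then $\alpha$ and $\beta$ are *proportional*: the
unlabeled data identify the direction of $\beta$, and only the scalar
scale must be learned from labels.

`fit_alpha()` estimates this direction by a LASSO-initialized adaptive
LASSO least squares over all $N$ pooled rows:

1. initial $\ell_1$ least squares with penalty $\mu_{\text{init}}$;
2. adaptive weights $\hat\omega_j = |\hat\alpha_{\text{init},j}|^{-\nu}$
   (default $\nu = 1$), features with a zero initial coefficient excluded;
3. weighted $\ell_1$ least squares with penalty $\mu$.

Both penalties are selected by BIC (the pooled sample is large, making CV
unnecessary and BIC fast).  `normalize_direction()` rescales to unit
$\ell_2$ norm with the first nonzero coordinate positive; the downstream
scale parameter $\rho$ absorbs the norm, so estimates of $\beta$ are
invariant while tuning grids become comparable across datasets.

## The prior adaptive estimator

The prior condition rarely holds exactly.  The prior adaptive
semi-supervised (PASS) estimator treats proportionality as a *preference*,
not a constraint, through the penalty

$$\lambda_1 \min_\rho \left\|(\beta - \rho\hat\alpha)_{\hat A}\right\|_1
  + \lambda_2 \left\|\beta_{\hat A^c}\right\|_1,
  \qquad \hat A = \operatorname{supp}(\hat\alpha),$$

added to the average logistic negative log-likelihood over the $n$ labeled
rows.  The first term pulls $\beta$ toward the closest multiple of the
surrogate direction; the second shrinks coefficients of features the
surrogate found irrelevant.  Large $(\lambda_1, \lambda_2)$ force
$\beta = \rho\hat\alpha$ (recovering the rigid two-step estimator valid
under the exact prior); $(\lambda_1, \lambda_2) \to 0$ recovers the
unbiased but high-variance supervised fit.  Cross-validation traverses
this bias–variance continuum automatically, which is what makes the
estimator robust to a bad surrogate.

Writing $\delta = \beta - \rho\hat\alpha$, the problem is an ordinary
weighted-$\ell_1$ logistic regression with covariates
$(S,\ X^\top\hat\alpha,\ X_1,\dots,X_p)$, parameters
$(\gamma, \rho, \delta)$, intercept and the first two covariates
unpenalized, factor 1 on $\hat A$ and $\kappa = \lambda_2/\lambda_1$ off
it.  `fit_pass()` solves it with glmnet and returns
$\hat\beta = \hat\delta + \hat\rho\hat\alpha$.

## Tuning parameters

* `lambda1` — penalty level on deviations from the surrogate direction
  inside $\hat A$.  Default grid: 100 log-spaced values from the largest
  per-$\kappa$ `lambda_max` down to 1% of it.
* `kappa` ($= \lambda_2/\lambda_1$) — relative penalty on features outside
  $\hat A$; default grid $\{0.25, 0.5, 1, 2, 4\}$.
* $(\lambda_1, \kappa)$ are tuned jointly by exhaustive 10-fold
  cross-validated deviance with a shared, seeded, $Y$-stratified fold
  split.  The source description leaves open whether the two levels were
  tuned jointly or via a fixed ratio; we tune jointly with a configurable
  $\kappa$ grid, and CV deviance is the default loss (held-out AUC is
  available by flag) since the tuning target is stated only as "prediction
  performance".  Ties prefer the larger $\lambda_1$, then the larger
  $\kappa$ (parsimony).
* `nu` — adaptive-LASSO exponent, default 1.
* Solver: penalized columns are internally standardized to unit sample SD
  (coefficients returned on the original scale); the unpenalized $S$ and
  $X^\top\hat\alpha$ columns are not.  Per-coefficient penalty factors are
  implemented by exact column rescaling, factor $\infty$ drops a column.

## Benchmarks

* `fit_lasso()` / `fit_alasso()` — supervised $\ell_1$ / adaptive-$\ell_1$
  logistic regression of $Y$ on $(S, X)$; $\beta$ penalized, $(\zeta,
  \gamma)$ not.
* `fit_ss_prior()` — the rigid two-step estimator: unpenalized logistic
  fit of $Y$ on $(1, S, X^\top\hat\alpha)$, $\beta = \hat\rho\hat\alpha$.
* `fit_plasso()` — prior LASSO: adds $\frac{\eta}{n}\sum_i
  \ell(Y^p_i, \cdot)$ to the likelihood, where the pseudo-labels $Y^p$ are
  predicted probabilities from either a partially penalized logistic model
  (variant 1; predictors inside $\hat A$ unpenalized) or the
  `fit_ss_prior()` model (variant 2).  $(\eta, \lambda)$ are tuned by
  joint shared-fold CV over $\eta \in \{0, 0.25, 0.5, 1, 2, 4\}$; the
  original prior-LASSO reference does not fix an $\eta$ rule, so this grid
  search is our interpretation.
* `fit_ulasso()` / `fit_ss_ulasso()` — unsupervised LASSO on extreme
  surrogate tails ($I(S > c_u)$ regressed on $X$ over rows with $S > c_u$
  or $S < c_l$; default quantiles 0.9/0.1, chosen so the tail
  probabilities are small), and its semi-supervised rescaling.

Preprocessing operators for real EHR tables are provided:
`log1p_counts()` ($x \mapsto \log(1+x)$ for count features, with an
optional flag-controlled application to the surrogate, itself a count) and
`orthogonalize_features()` (residualize every feature on (intercept,
healthcare utilization), since high-utilization patients have elevated
counts across the board; the intercept makes residuals mean-free, matching
standard practice — the source is silent on it).

## The simulation engine

`generate_main_study()` emulates zero-inflated, right-skewed,
autocorrelated EHR count features: $Z \sim N(0, \Sigma)$ with
$\sigma_{ij} = 4 \cdot 0.5^{|i-j|}$, $X = h(Z)$ with
$h(t) = \log(1 + [e^t])$ ($[\cdot]$ = nearest integer; exact halves round
to even, base R's convention — the choice is immaterial since $e^t$ hits a
half-integer on a null set), surrogate $S = h(1 + X^\top\alpha_0 +
\epsilon)$, $\epsilon \sim N(0, 2^2)$, and outcome
$\operatorname{logit}\Pr(Y{=}1) = -4 + 0.5\,S + X^\top\beta_0$.  Six
coefficient templates span identical directions (I), small perturbations
(II), support mismatches in both directions (III, IV), shared support with
different magnitudes (V), and essentially disjoint supports (VI).
Defaults ($p = 500$, $N = 10000$, test size 10000) are the stated study
conditions.  The first $n$ generated rows are labeled, the next $N - n$
unlabeled, and the test rows continue the same seeded stream, so a study
is bit-reproducible from its spec.

`generate_misspec_study()` violates the assumptions deliberately: uniform
margins $X = 2\Phi(Z) - 1$ on two independent AR(1) blocks (features 1–20
and 21–$p$), a probit-threshold outcome (so the logistic model itself is
misspecified), and $S = \mu Y + \eta_1^\top X + Y \eta_2^\top X +
\epsilon_s$ with scenario-specific $(\mu, \eta_1, \eta_2)$ ranging from
the exact prior (i) to strong violations (iii).  The estimand is the
population minimizer of the expected logistic risk;
`oracle_limit_coefficients()` approximates it by an unpenalized logistic
fit on a fresh Monte-Carlo sample (default $5 \times 10^5$ rows, a size at
which coefficient MC error is ~0.01) restricted to the generative block
1–20 — the block covariance makes the remaining features exactly
independent of $(Y, S, X_{1..20})$, so their limit coefficients are zero
by construction.  The MC seed is fixed in the spec so the limit is shared
and cached across replications.

What a green simulation test does **not** establish: the generator draws
i.i.d. rows from a stationary, fully specified law.  Real EHR data have
patient-level heterogeneity in utilization, informative missingness,
temporal drift, and labeled subsets that are rarely uniform random draws.
Results under the generator certify the estimator's behavior under its
stated assumptions (and controlled violations of them), not performance on
any particular health system's records.

## Numerical choices

* Solver backend: glmnet, with its conventions measured and compensated
  (its gaussian objective divides the RSS by $2n$, observation weights are
  normalized by their sum, and penalty factors are rescaled to sum to the
  number of variables); our objectives are $(1/n)\,\text{RSS}$ and the
  average logistic NLL, with KKT certificates computed directly.
* `lambda_max` is the exact KKT threshold at the null fit under those
  objectives — for the linear family this carries the factor 2 from
  $\frac{d}{d\beta}(1/n)\text{RSS}$.
* Convergence thresholds: glmnet `thresh` $10^{-10}$ for path fits,
  $10^{-12}$ where tests compare against an independent proximal-gradient
  oracle; KKT tolerance $10^{-4}$ for the `converged` flag.
* Degenerate inputs: a zero surrogate direction drops the $\rho$ column
  and PASS degrades to a supervised LASSO at $\lambda_2$ (documented
  behavior, not an error); logistic separation in unpenalized fits falls
  back to a small ridge with a warning; constant columns are dropped
  (collinear with the intercept).
* BIC ties choose the larger penalty; CV ties the larger $\lambda_1$, then
  the larger $\kappa$.

## Known limitations

* No inference (standard errors, intervals) for the fitted coefficients.
* Single surrogate only; the multiple-surrogate extension is out of scope.
* The cross-validated 2-D grid search is exhaustive; for very large
  $\kappa$ grids a fixed-ratio search would be cheaper.
* The pseudo-label weight grid for the prior LASSO is a pragmatic default,
  not a reproduction of the original authors' (unpublished) rule.
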