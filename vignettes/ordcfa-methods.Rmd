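---
title: "Interval estimation for factor correlations in ordinal CFA: models, estimators, and simulation design"
author: "ordcfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval estimation for factor correlations in ordinal CFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordcfa)
```

## The problem

Questionnaire items are usually ordered categories, yet the quantities of
substantive interest — here the correlation $\xi$ between two latent
traits — live on a continuous scale. The standard ordinal confirmatory
factor analysis (CFA) model assumes each observed item $y_i$ discretizes a
latent continuous response $y_i^*$ at strictly increasing thresholds
$\tau_{i,1} < \tau_{i,2} < \tau_{i,3}$ (four categories), with

$$y^* = \Lambda \omega + \varepsilon, \qquad
\Sigma(\Lambda, \Phi) = \Lambda \Phi \Lambda' + I - \mathrm{diag}(\Lambda \Phi \Lambda'),$$

where $\Lambda$ is a $10 \times 2$ simple-structure loading matrix (items
1–5 on factor 1, 6–10 on factor 2), $\Phi$ is the $2 \times 2$ factor
correlation matrix with off-diagonal $\xi$, and each $y_i^*$ has unit
variance, so the error variances are tied to the loadings,
$\theta_i = 1 - \lambda_i^2$.

Point estimates of $\xi$ are only half the story: a point estimate with a
plausible-looking standard error can still produce intervals that rarely
contain the truth. This package provides the machinery to study exactly
that — coverage, width, and directional bias of *interval* estimates of
$\xi$ — for six estimators in small samples: Bayesian credibility
intervals under two priors, and Fisher-z confidence intervals from four
polychoric-based fits (WLS, robust DWLS, robust ULS, robust ML).

## Synthetic data

`generate_dataset()` draws, per replication, loadings i.i.d. from
Uniform(0.4, 0.8), builds $y^*$ with independent normal errors of variance
$1 - \lambda_i^2$, and discretizes. Two factor-score regimes:

* **normal** — bivariate standard normal scores with correlation $\xi$,
  via the Cholesky factor of $\Phi$;
* **mild_skew** — each margin a Fleishman cubic
  $a + bZ + cZ^2 + dZ^3$ of correlated normals, the normals generated at
  the Vale–Maurelli *intermediate correlation* (the root of the cubic
  relating pre- and post-transform correlations), then re-standardized to
  sample mean 0 and sd 1 so the factor-score scale is held exactly.

A point worth documenting: the targeted moments of the skewed condition —
skewness 1.5 with excess kurtosis 1.5 — are **outside** the feasible
region of the cubic power method. At skewness 1.5 the smallest attainable
excess kurtosis is about 2.37; no cubic transform of a normal can produce
that pair, and generators that appear to do so silently return an
approximation. `fleishman_coefficients()` makes this explicit: it errors
on infeasible targets by default, and with `on_infeasible = "nearest"`
(used by the generator) returns the closest attainable pair with unit
variance held exact — skewness $\approx 1.30$, excess kurtosis
$\approx 1.55$. The "mildly skewed" study condition is therefore exactly
that: mildly skewed.

**Thresholds.** The generating thresholds are a design choice the
literature often leaves implicit. The default is standard-normal quartile
cut-points $(\Phi^{-1}(0.25), 0, \Phi^{-1}(0.75))$ for every item —
balanced categories, the least assumptive option — exposed as a
`model_spec()` field so sensitivity to unbalanced categories can be
explored. This choice matters: balanced categories give unusually stable
polychoric correlations, so solution-failure rates for estimators whose
weak point is raw polychoric noise (notably ML on the polychoric matrix
at $n \le 63$) sit below what studies with unbalanced or unstated
thresholds report, while failure modes driven by weight-matrix
conditioning (WLS) are insensitive to it.

## Two-step polychoric estimation and the ACM

`polychoric()` follows the classical two-step procedure: item thresholds
from marginal cumulative proportions
($\hat\tau_{i,k} = \Phi^{-1}(\hat F_{i,k})$), then each of the 45
pairwise correlations by maximizing the bivariate-normal
contingency-table likelihood over $\rho$ alone with thresholds held
fixed. Estimates are clipped to $[-0.999, 0.999]$, with boundary hits
flagged and counted as inadmissible downstream. Empty leading/trailing
categories are collapsed per item; a column with a single observed
category is an error. The vectorization order — column-major lower
triangle, $(2,1), (3,1), \dots, (10,9)$ — is fixed package-wide.

The rectangle probabilities use a vectorized bivariate-normal CDF
(`pbinorm()`), the single-integral Drezner–Wesolowsky representation
evaluated with 64-point Gauss–Legendre quadrature; it agrees with
`mvtnorm::pmvnorm` to near machine precision across $|\rho| \le 0.999$
and evaluates the millions of cell probabilities a study requires in
vectorized batches.

The asymptotic covariance matrix (ACM) $\hat\Gamma$ of the correlation
vector — the weight source for WLS/DWLS and all sandwich standard
errors — is estimated from per-observation estimating-function
contributions. Two variants:

* `"score"` (default): outer products of the pairwise-likelihood scores
  in $\rho$ with thresholds treated as fixed, matching the "thresholds
  held constant" logic of the second step. This is the convention whose
  small-sample behavior reproduces the classical WLS failure pattern.
* `"score-adjusted"`: the full two-step sandwich, stacking the threshold
  estimating equations and propagating first-step error through the
  block-triangular Jacobian. It is better calibrated in principle but
  markedly worse conditioned at small $n$.

A structural fact the package leans on: with $n$ observations the score
outer-product matrix has rank at most $n$, so with 45 correlations the
ACM cannot be positive definite when $n = 42$. Full-weight WLS is then
infeasible — not a numerical accident but a property of the design — and
`cfa_fit()` records `"acm-not-pd"` non-convergence for every replication
at that sample size. A delete-one jackknife ACM (`"jackknife"`) is
provided for cross-checking; $\hat\Gamma$ is kept on the
$\sqrt{n}(r - \rho)$ scale, with consumers dividing by $n$, so the
scaling convention lives in exactly one place.

## Least-squares and ML fitting

`cfa_fit()` minimizes
$F(r; \lambda, \xi) = [r - \rho(\lambda, \xi)]' V [r - \rho(\lambda, \xi)]$
over the 10 loadings and $\xi$, where $\rho(\lambda, \xi)$ collects the
below-diagonal elements of $\Lambda \Phi \Lambda'$
($\lambda_i\lambda_j$ within a factor, $\lambda_i\lambda_j\xi$ across),
with $V = \hat\Gamma^{-1}$ (WLS), $V = \mathrm{diag}(\hat\Gamma)^{-1}$
(RDWLS), or $V = I$ (RULS). RML minimizes the ML discrepancy
$\log|\Sigma(\theta)| - \log|R| + \mathrm{tr}(R\,\Sigma(\theta)^{-1}) - p$
on the polychoric matrix $R$ (requiring $R$ positive definite; a non-PD
$R$ is recorded as non-convergence). Gradients are analytic throughout
(the Jacobian $\Delta = \partial\rho/\partial\theta$ has closed form and
is finite-difference-checked in the tests); optimization is
box-constrained quasi-Newton (L-BFGS-B) with $|\lambda_i|, |\xi| < 0.999$
and deterministic scale-aware starts (common loading from the mean
within-block correlation, $\xi$ from the cross-block mean). Convergence
requires a zero optimizer status and a projected-gradient norm below
$10^{-5}(1 + F)$.

**Classification.** Non-convergence and inadmissibility are disjoint
states with non-convergence taking precedence. A converged fit is
inadmissible if any parameter is pinned at the Heywood bound (a loading
at 0.999 means the unconstrained optimum wants $|\lambda| \ge 1$, i.e. a
negative implied error variance), or a boundary-clipped polychoric fed
the fit. Only converging-and-admissible replications contribute to
interval and point diagnostics; the tallies keep the full accounting so
that survivor bias in those diagnostics stays visible.

**Standard errors and intervals.** Intervals for $\xi$ use Fisher's z
transformation. Two standard errors are computed and stored:

* the classical Fisher-z standard error, $se_z = 1/\sqrt{n-3}$,
  equivalently $se_\xi = (1-\hat\xi^2)/\sqrt{n-3}$ — the convention
  behind standard correlation-interval output in the SEM software this
  design emulates. It treats $\hat\xi$ as if it were a sample
  correlation, ignores loading-estimation noise entirely, and is the
  default interval SE (`se = "fisherz"`);
* the ACM sandwich
  $(\Delta'V\Delta)^{-1}\Delta'V\hat\Gamma V\Delta(\Delta'V\Delta)^{-1}/n$
  (collapsing to $(\Delta'\hat\Gamma^{-1}\Delta)^{-1}/n$ for WLS; for RML
  the weight is the expected ML weight
  $V_{ab,cd} = \Sigma^{-1}_{ac}\Sigma^{-1}_{bd} + \Sigma^{-1}_{ad}\Sigma^{-1}_{bc}$
  at the optimum), selectable via `se = "sandwich"`.

The naive default is deliberate: the undercoverage and
standard-error-underestimation phenomena this machinery is built to
measure are properties of that convention (the sandwich SE is roughly
calibrated — its intervals cover near nominally — which is itself an
informative comparison available by switching one argument).

## The Gibbs sampler

`bayes_fit()` targets the same model with the identification
$\theta_j = 1 - a_j^2$ and priors: loadings standard normal truncated to
$(0, \infty)$, thresholds standard normal with enforced ordering, factor
means $\mu_f \sim N(0,1)$, and $\xi$ uniform on $(-1,1)$ (relatively
less informative) or $(0,1)$ (informative). Data augmentation makes the
conditionals tractable: each latent response is a truncated normal draw
within the threshold bin of its observed category (step b), each interior
threshold a truncated standard-normal draw between the extreme latent
responses of its adjacent categories (step a), and the structural block
(step c) updates loadings, factor means, factor scores and $\xi$.

The structural updates are **partially collapsed**: the factor means,
each loading, and $\xi$ are updated against the marginal likelihood
$y^*_t \sim N(\Lambda\mu,\; \Lambda\Sigma_\xi\Lambda' + \Theta)$ with the
factor scores integrated out (cheap $10\times10$ Cholesky evaluations),
and the scores are redrawn from their bivariate-normal full conditional
afterwards. The uncollapsed textbook scheme is valid but mixes
pathologically here: conditioning on the scores leaves $\xi$ a
conditional an order of magnitude narrower than its marginal posterior
(effective sample sizes in the single digits per 800 draws), and the
free factor means ride a weakly identified location ridge against the
thresholds. Collapsing raises the $\xi$ effective sample size by roughly
twenty-fold and is what makes the convergence rule below attainable at
realistic chain lengths. Loadings and $\xi$ use random-walk
Metropolis-within-Gibbs with proposals reflected at the support bounds
and scales adapted toward a mid-range acceptance rate during burn-in
only.

Posterior summaries are equal-tailed 2.5%/97.5% quantile intervals and
the EAP (posterior mean) over chains pooled after burn-in; defaults
mirror the reference configuration of 10,000 burn-in and 2,000 retained
updates, with 3 chains started at over-dispersed prior quantiles of
$\xi$.

**Diagnostics.** `mpsrf()` implements the Brooks–Gelman multivariate
potential scale reduction factor on the scale-reduction (square-root)
scale, with the $(m+1)/m$ chain-count factor of the original paper
(a widely used reference implementation substitutes $1 + 1/\text{nvar}$;
the tests encode the exact relationship). Convergence is judged by
MPSRF $< 1.2$ over $(\xi, a_1, \dots, a_{10})$. The diagnostic is a
noisy maximum-eigenvalue statistic: with few retained draws it can
exceed 1.2 on well-mixed chains, which is why the retained-sample
defaults are what they are. `heidelberger_welch()` is a native
implementation of the classical stationarity/half-width procedure
(second-half AR spectral estimate, asymptotic Cramér–von-Mises critical
values, progressive 10% trimming) — a popular wrapper variant proved
insensitive even to eight-sigma level shifts because it renormalizes by
a spectral estimate contaminated by the shift itself. With trimming, an
early disturbance yields a pass with a reduced usable fraction; only
non-stationarity persisting through every trimmed window fails outright.

## Diagnostics over replications

For each design cell and method, over converging-and-admissible
replications: coverage (fraction of intervals containing the generating
$\xi$), mean width, positive/negative interval bias (intervals entirely
above/below the truth — with coverage these partition the usable set),
RMSE and mean bias of the point estimates, and the standard-error
calibration pair $\mu_{se}$ (mean reported SE) vs $\sigma_\mu$ (SD of
the point estimates), whose ratio diagnoses under/overestimation.
`eta_squared()` runs fixed-effects factorial ANOVAs of cell-level
outcomes on method, sample size, distribution and $\xi$ (main effects
plus two-way interactions, higher orders pooled into the residual, one
value per design cell as the unit of analysis) and reports
$100 \cdot SS_{\text{effect}}/SS_{\text{total}}$, which sums to 100 with
the residual — effect sizes for pattern detection, not significance
tests.

## The study runner

`run_study()` crosses 2 distributions × 3 correlations
(0.2, 0.5, 0.8) × 6 sample sizes (42–315) × 6 methods. Within a
replication every method sees the *same* dataset (and the four
least-squares fits share one polychoric estimation), so method
comparisons are paired. Seeds derive deterministically from the master
seed per (cell, replication), so any cell reproduces in isolation and
results are identical for any worker count. The shipped `"desk"` profile
(100 replications, 2 chains × 1,000 retained) is sized for interactive
use; `"full"` selects the full 500-replication, 3-chain configuration.

## Problem sizes used by the tests and the acceptance script

The test suite runs reduced Monte-Carlo scales chosen to keep the whole
suite under a coffee break while leaving the agreement bands meaningful:
solution accounting at 249 replications per condition, the $n = 315$
interval cells at 150–200 replications, Bayesian coverage at 20
replications with 2 chains × 1,500 retained draws, and the MPSRF
reference configuration (3 chains × 2,000) on four datasets. The
acceptance script runs the frequentist cells at the full 500
replications and sweeps the Gibbs sampler over 12 datasets covering
every sample size and both distributions (3 chains, 2,000 burn-in +
3,000 retained each; the larger retained sample keeps the
max-of-many-eigenvalues MPSRF statistic comfortably inside its own
sampling noise). Monte-Carlo agreement for a
proportion $p$ at $R$ replications is judged within
$3\sqrt{p(1-p)/R}$, and means within three empirical standard errors.

## What the generator does and does not emulate

Passing tests show that the estimators behave as described **under the
generating model**: simple structure with no cross-loadings, identical
balanced thresholds across items, uncorrelated errors, complete data,
and at most mild non-normality (skewness ~1.3 — the attainable version
of the nominal condition). Real Likert data bring unbalanced and
item-specific thresholds, cross-loadings, correlated residuals and
missingness; none of these are exercised, and conclusions about, e.g.,
solution-failure rates are sensitive especially to the threshold
configuration. The generator's threshold field is the intended knob for
such sensitivity work.

## Known limitations

* RML here is ML-on-polychorics with ACM sandwich SEs available; no
  Satorra–Bentler-type scaled test statistics are computed (no fit
  statistics are in scope).
* The optimizer's convergence thresholds are declared, not matched to
  any specific commercial implementation; non-convergence counts are
  comparable in kind, not in decimal.
* Polyserial/Pearson mixtures, more than two factors, and category
  counts other than four are out of scope (the internals are
  parameterized, but only the 2 × 5-item, 4-category design is tested).
* The Bayesian model samples free factor means per the prior
  specification; their weak identification against the thresholds is
  handled by collapsed updates rather than by fixing them, so their
  posteriors are wide and slow-mixing by construction — they are
  monitored for neither convergence nor inference.
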