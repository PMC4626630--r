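# ordcfa

Interval estimation for factor correlations in ordinal confirmatory
factor analysis (CFA), and the Monte-Carlo machinery to evaluate it.

## The problem

Likert-type items are ordered categories assumed to discretize latent
continuous responses at thresholds. For a two-factor ordinal CFA

    y* = Λω + ε,    Σ(Λ, Φ) = ΛΦΛ′ + I − diag(ΛΦΛ′),

the quantity of interest is the factor correlation ξ (the off-diagonal
of Φ). In small samples, point estimates of ξ can look reasonable while
the *intervals* around them are badly miscalibrated — too narrow, and
more often entirely above the truth than below it. Quantifying that
requires simulating the whole pipeline: data generation, polychoric
correlation estimation, model fitting, interval construction, and
coverage accounting.

`ordcfa` implements that pipeline for researchers in psychometrics and
methodology:

* **Synthetic ordinal data** — five 4-category items per factor,
  loadings drawn from Uniform(0.4, 0.8), factor scores either bivariate
  normal (Cholesky) or mildly skewed via the Vale–Maurelli / Fleishman
  cubic transform with the intermediate-correlation adjustment.
* **Two-step polychoric estimation** — thresholds from marginal
  frequencies, pairwise correlations by contingency-table likelihood
  with thresholds held fixed, plus a score-based estimate of the
  asymptotic covariance matrix (ACM) of the 45 correlations.
* **Four least-squares/ML fits** of (Λ, ξ) to the polychoric vector r by
  minimizing [r − ρ(Λ,Φ)]′V[r − ρ(Λ,Φ)] with V = Γ̂⁻¹ (WLS),
  diag(Γ̂)⁻¹ (RDWLS), I (RULS), or the ML discrepancy on the polychoric
  matrix (RML); Fisher-z confidence intervals for ξ; ACM sandwich
  standard errors available; Heywood-case and non-convergence
  classification.
* **A Gibbs sampler with data augmentation** for the Bayesian model
  under informative (ξ ~ Unif(0,1)) and relatively-less-informative
  (ξ ~ Unif(−1,1)) priors, with partially collapsed structural updates,
  Brooks–Gelman MPSRF and Heidelberger–Welch diagnostics, EAP and
  equal-tailed credibility intervals.
* **Replication diagnostics** — coverage, width, positive/negative
  interval bias, RMSE, bias, standard-error calibration (μ.se vs σ.μ),
  solution tallies, and η² effect sizes from factorial ANOVAs.
* **A study runner** crossing 2 distributions × 3 correlations × 6
  sample sizes × 6 methods with paired (shared-data) replications and
  fully deterministic per-cell seeding.

## Worked example

```r
library(ordcfa)
set.seed(42)
spec <- model_spec(draw_loadings(), factor_correlation = 0.5)
d  <- generate_dataset(spec, n = 200, seed = 7)
pc <- polychoric(d)
cfa_fit(pc, method = "RULS")
cfa_fit(pc, method = "RML")
bayes_fit(d, prior_spec("lessinf"), n_chains = 2,
          n_burn = 1000, n_keep = 1500, seed = 11)
```

```
RULS fit (n = 200): xi = 0.4270 (se 0.0583), 95% CI [0.3064, 0.5341]
RML fit (n = 200): xi = 0.4245 (se 0.0584), 95% CI [0.3037, 0.5319]
Bayesian ordinal CFA (lessinf prior, 2 chains x 1500 kept)
  xi: EAP = 0.4022, posterior SD = 0.0836, 95% CI [0.2283, 0.5527]
  MPSRF = 1.1128
```

Reading this: the generating truth is ξ = 0.5. Both least-squares fits
land near 0.43 with Fisher-z intervals of width ≈ 0.23 that contain the
truth; the reported `se` is the classical Fisher-z standard error
(1 − ξ̂²)/√(n − 3), which ignores loading-estimation noise (pass
`se = "sandwich"` for the ACM-propagated alternative). The Bayesian EAP
is 0.40 with a wider credibility interval — posterior uncertainty under
a flat prior on (−1, 1) — and an MPSRF of 1.11, under the conventional
1.2 convergence bound.

A full factorial experiment is one call:

```r
des <- study_design(profile = "desk")   # 100 reps, 2 chains x 1000 kept
st  <- run_study(des, out_dir = "study-out")
```

which writes per-replication records, per-cell summaries (coverage,
width, interval bias, RMSE, bias, μ.se, σ.μ, failure tallies) and η²
tables, plus a JSON manifest of the configuration and seeds.

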