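---
title: "Models and methods behind phyloprev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyloprev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phyloprev` treats species-level disease prevalence — for example, the
fraction of necropsy records of a species carrying a malignancy diagnosis —
as a continuous evolutionary trait on a phylogeny. This vignette documents
the statistical models, the estimation choices and the synthetic-data
design, including every place where a judgement call was required.

## Trait models and their covariance structures

All analyses rest on the shared-time matrix $t_{ij}$: the summed branch
length from the root to the most recent common ancestor of species $i$ and
$j$, with $t_{ii}$ the root-to-tip distance. Under a given evolutionary
model the tip values are multivariate normal with a mean vector and a
variance–covariance matrix (VCV) built from $t_{ij}$:

| kind | covariance $V_{ij}$ | mean | shape parameter |
|------|--------------------|------|-----------------|
| `bm` | $\sigma^2 t_{ij}$ | $z_0$ | — |
| `ou` | $\frac{\sigma^2}{2\alpha}(1 - e^{-2\alpha t_{ij}})$ | $z_0$ | pull $\alpha > 0$ |
| `eb` | $\sigma^2 (e^{a t_{ij}} - 1)/a$ | $z_0$ | burst decay $a \le 0$ |
| `lambda` | $\lambda \sigma^2 t_{ij}$ off-diagonal, $\sigma^2 t_{ii}$ on it | $z_0$ | signal $\lambda \in [0,1]$ |
| `delta` | $\sigma^2 t_{ij}^{\delta}$ | $z_0$ | time power $\delta > 0$ |
| `kappa` | Brownian VCV of the tree with branch lengths $b^{\kappa}$ | $z_0$ | branch power $\kappa \in [0,1]$ |
| `rate_trend` | $\sigma^2 (t_{ij} + s\, t_{ij}^2/2)$ | $z_0$ | rate slope $s$ |
| `mean_trend` | $\sigma^2 t_{ij}$ | $z_0 + d\, t_{ii}$ | drift $d$ |
| `white` | $\sigma^2$ on the diagonal, 0 elsewhere | $z_0$ | — |

Three constructions deserve comment.

* **Ornstein–Uhlenbeck.** The default (`ou_form = "rooted"`) is the
  non-stationary form $\frac{\sigma^2}{2\alpha}(1-e^{-2\alpha t_{ij}})$,
  which conditions on the root state. The stationary (Hansen) form
  multiplies this by $e^{-\alpha d_{ij}}$ with $d_{ij}$ the patristic
  distance, and is available as `ou_form = "hansen"` for cross-checks
  against implementations that use it. On ultrametric trees the two differ
  only in how much weight recent shared history carries.
* **Rate trend.** A covariance proportional to $1 + s\,t_{ij}$ is not a
  valid diffusion covariance: it does not vanish as shared time goes to
  zero. We therefore treat $\sigma^2(1 + s t)$ as the *instantaneous* rate
  and use its time integral $\sigma^2 (t_{ij} + s t_{ij}^2/2)$, which
  vanishes at $t_{ij}=0$ and reduces to Brownian motion at $s = 0$. The
  slope is bounded below by $-2/T$ ($T$ = tree height) so every variance
  stays positive.
* **Kappa.** Applied per branch ($b \mapsto b^{\kappa}$, with $0^0 = 1$),
  i.e. Brownian motion on the transformed tree, rather than the shorthand
  $t_{ij}^{\kappa}$ applied to path sums; the two differ whenever paths
  contain more than one branch.

The mean trend is rejected on ultrametric trees with an explanatory error:
when every tip sits at the same depth, $z_0$ and the drift are perfectly
confounded.

## Maximum-likelihood fitting

`fit_model()` maximizes the multivariate normal likelihood. The root state
(and the drift, for the mean trend) is profiled analytically by generalized
least squares at every candidate covariance. With exact tip values
(no measurement error) the rate also has a closed-form profile,
$\hat\sigma^2 = q/n$ with $q$ the GLS residual quadratic form, leaving at
most one bounded shape parameter which is optimized by a scalar search over
its interval, guarded by a five-point scan so boundary optima
($\lambda = 0$ or $1$, for instance) are never missed.

With per-species standard errors the covariance is
$\sigma^2 R(\theta) + \mathrm{diag}(se^2)$ and $\sigma^2$ no longer profiles
in closed form; `fit_model()` then runs a bounded quasi-Newton search over
$(\log \sigma^2, u)$ where $u$ is a transformed shape parameter: $\alpha$
and $\delta$ are searched on the log scale and the rate-trend slope on a
shifted log scale $\log(s + 2/T)$, which keeps the search well-conditioned
near the singular lower bound. Starts are placed at scientifically neutral
values (e.g. $\alpha T = 1$, $\lambda = 0.7$) with optional additional
restarts. Parameter bounds are fixed once: $\lambda, \kappa \in [0,1]$,
$\delta \in (0, 3]$, $\alpha \in (10^{-8}, 50/T]$, $a \in [-10/T, 0]$,
$s \in (-2/T, 10/T]$.

Prevalence data are arcsine-square-root transformed
($y = \arcsin\sqrt{p}$) *before* any fitting or regression. On this scale
the sampling error of a proportion estimated from $n$ records is
$1/(2\sqrt{n})$ by the delta method, independent of the proportion — the
variance-stabilizing property that motivates the transform. This closed
form is used wherever a response standard error is needed.

Model comparison uses AIC ($2k - 2\log L$), not AICc; the parameter count
is 2 for Brownian motion and white noise and 3 otherwise. All-equal trait
vectors are returned as degenerate fits ($\hat\sigma^2 = 0$) rather than
errors, since they arise naturally in small simulations.

## Clade-level model selection

`best_model()` applies the decision rule that a model is a *decisively*
better fit only when its AIC is at least 10 points below the runner-up;
anything closer is weak evidence. `hierarchical_assignment()` extends this
to clades: each clade is refit with every candidate kind on its pruned
subtree, keeps its own winner only when the win is decisive, and otherwise
inherits the model assigned to its parent grouping, so a group must
demonstrate a significant deviation in fit before its assumptions diverge
from its ancestors'. Clades under 10 species are not refit (three-parameter
maximum likelihood on tiny clades is unstable) and inherit directly; both
the threshold and the minimum size are exposed as arguments. Whether to
refit all candidates per clade or only the contenders was an open choice;
all candidates are refit.

## Measurement-error phylogenetic regression

`pgls_sey()` is generalized least squares with residual covariance
$\sigma^2 R + \mathrm{diag}(se_y^2)$, where $R$ is the unit-rate VCV of a
chosen model with its shape fixed. $\sigma^2$ is estimated by maximum
likelihood (ML, not REML) with the coefficients profiled; Wald t tests use
$n - 2$ degrees of freedom. Because $\sigma^2$ is ML, reported standard
errors with a white structure and zero measurement error differ from
ordinary least-squares ones by exactly $\sqrt{(n-2)/n}$; estimates agree to
machine precision.

`pgls_sey_optim()` first fits the candidate kinds (Brownian motion, OU,
Pagel's $\lambda$, $\delta$, $\kappa$, white noise, rate trend) to the
*response* with its measurement error, selects the lowest-AIC kind — the
plain best fit, no decisiveness gate, though one can be switched on — and
then runs the regression under the selected structure with its fitted shape
held fixed. Selecting on the response mirrors fitting evolutionary models
to the disease trait itself before trend estimation.

## The binomial GEE comparator

`gee_binomial()` is the occurrence-count alternative: quasi-binomial
regression of per-species occurrence proportions with logit link, variance
$\mu(1-\mu)/n_i$, and the Brownian correlation
$t_{ij}/\sqrt{t_{ii} t_{jj}}$ as a fixed working correlation, solved by
Fisher scoring in correlation space (the fixed correlation is factorized
once, so iterations cannot degenerate when fitted prevalences approach the
boundaries; a trust-region cap bounds each step). Wald tests use $n-2$
degrees of freedom.

Species-level prevalence is far more variable than binomial sampling alone
predicts, so the raw binomial variance underestimates the truth
(overdispersion) and inflates test statistics. Three covariance flavours
are provided: `"glm"` (default) takes the coefficient covariance from the
dispersion-scaled independence quasi-binomial fit, which is how the
established phylogenetic GEE implementation reports binomial standard
errors; `"naive"` is the model-based GEE covariance scaled by the Pearson
dispersion; `"naive-unscaled"` omits the dispersion correction entirely and
exposes the full inflation. On some datasets (observed proportions exactly
0 or 1 combined with a nearly singular correlation) the estimating equation
has no solution; such fits raise a separation error, and the simulation
harness records them as method failures rather than silently imputing a
p-value.

## Ancestral state reconstruction

`lambda_rescale()` injects a fitted signal $\lambda$ into an ultrametric
tree by multiplying internal branches by $\lambda$ and extending terminal
branches to preserve tip depths — exactly reproducing the $\lambda$-model
covariance (off-diagonals scaled, diagonals unchanged). Non-ultrametric
input is rejected for this operation.

`anc_ml_bm()` computes joint maximum-likelihood ancestral states under
Brownian motion: with the rate fixed at its tip-based ML estimate, the node
states solve the inverse-branch-length-weighted tree Laplacian system (each
node is the weighted compromise of its neighbours), and per-node variances
are the conditional variances of the states given the tips — the diagonal
of the inverse internal-node block of the Laplacian precision, scaled by
$\hat\sigma^2$. Confidence intervals are $\pm 1.96$ standard deviations; no
uncertainty in $\hat\sigma^2$ itself is propagated, matching standard ML
reconstruction practice. The root estimate coincides exactly with the GLS
root state of the Brownian fit. `asr_lambda_bm()` chains fit → rescale →
reconstruct into the full prevalence-reconstruction pipeline.

## The synthetic comparison study

`sim_config()`/`run_grid()` reproduce a method-comparison experiment on
fully synthetic data. Each trial draws:

1. an ultrametric pure-birth tree, height normalized to 1 (the height
   normalization makes all time-scaled parameter bounds tree-scale-free);
2. per-species record counts from a negative binomial (mean 15, dispersion
   0.8 — a heavy right tail resembling zoological record databases),
   rejection-resampled to a minimum threshold of 1, 5, 10 or 20;
3. a predictor evolved on the tree under the cell's generating model with
   unit rate (Brownian motion; OU with $\alpha = 2$, a moderate pull at
   $\alpha T = 2$; or Pagel's $\lambda = 0.5$, an intermediate signal —
   both values chosen once as representative of empirical prevalence data);
4. a response $y = b\,x + \varepsilon$ with $b \sim U(-2, 2)$ and
   $\varepsilon \sim N(0, 0.05^2)$, mapped onto the admissible arcsine
   interval $[0.02, \pi/2 - 0.02]$ by a rank-preserving affine squash; the
   noise is added *before* the squash so that the signal-to-noise ratio —
   and hence the difficulty of detecting weak slopes — survives the map.
   Null cells draw predictor and response as independent standard normals;
5. occurrence counts $k_i = \mathrm{round}(p_i n_i)$ from the same latent
   prevalence (a binomial draw is available behind a flag).

The regression methods observe the *realized* prevalence $k_i/n_i$
(arcsine-transformed) with declared error $1/(2\sqrt{n_i})$ — this is what
carries the record-count dimension into the error rates: at a minimum of
one record, many species contribute nearly binary prevalence estimates.

Errors are scored at $p = 0.05$: false positives on null cells, false
negatives on trend cells; per-method grand means pool all cells
unweighted. Per-trial seeds are split from the master seed through a single
stream, so the grid is bitwise reproducible. The shipped comparison (the
acceptance script and the heavier tests) uses species counts 50 and 150
with 100 replicates per cell — sizes chosen to keep the full comparison
reproducible on a single desk-scale core — and checks the growth of the
GEE's false-positive rate with species count on dedicated GEE-only null
cells at 350 species.

What the generator does *not* emulate: real life-history predictors (the
predictor is itself model-generated), a real time-calibrated supertree,
phylogenetically structured record counts, or correlated multi-trait
evolution. Passing the comparison therefore shows that the methods rank and
calibrate as expected under controlled misspecification, not that any
particular empirical dataset will reproduce specific numbers.

## Numerical notes and limitations

* Likelihood evaluations use Cholesky factorizations throughout; a
  structure matrix that fails to factorize is treated as `-Inf` likelihood
  rather than an error during optimization.
* Small-parameter limits use `expm1` so the early-burst and OU structures
  collapse to Brownian motion to machine precision.
* `simulate_traits()` falls back to an eigenvalue square root for
  positive-semidefinite but singular covariances (e.g. $\lambda = 0$ with
  duplicated tip depths).
* Newick output keeps 15 significant digits so read/write round trips
  preserve branch lengths to $10^{-12}$.
* Zero-length branches are admitted; weights $1/b$ in the reconstruction
  Laplacian are capped at $10^{12}$.
* The package does not implement multivariate trait models, discrete-state
  models, phylogenetic independent contrasts, Bayesian fitting, or the
  negative-binomial mixed-model alternative to the binomial GEE.
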