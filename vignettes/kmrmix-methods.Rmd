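---
title: "Kernel machine regression for exposure mixtures: models and methods"
author: "kmrmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel machine regression for exposure mixtures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kmrmix)
```

## The model

Studies of multi-pollutant mixtures need to estimate how M concurrent
exposures jointly relate to a health outcome when the relationship may be
nonlinear and non-additive. A fully saturated basis-expansion model is
hopeless even at moderate M: with a DF-degree-of-freedom basis per exposure
and all interactions, the parameter count is `(1 + DF)^M - 1`
(`saturated_model_parameter_count()`), e.g. 255 parameters for four
exposures with cubic-spline flexibility. Kernel machine regression
regularizes this surface instead of enumerating it. The continuous-outcome
model is

y_i = h(z_i1, ..., z_iM) + x_i' beta + eps_i,  eps_i ~ N(0, sigma^2),

where the unknown surface h gets a Gaussian-process prior induced by the
component-weighted Gaussian kernel

K(z, z') = exp{ -sum_m r_m (z_m - z'_m)^2 }.

Two individuals with similar exposure profiles therefore have similar
values of h. The weight r_m is an inverse squared length scale for
exposure m; r_m = 0 removes exposure m from the surface entirely, which is
what makes the kernel a vehicle for variable selection.

### Marginalized sampling

Writing h = (h_1, ..., h_n) at the observed exposures, the model is the
mixed model y ~ N(X beta, sigma^2 (I + lambda K)), with
lambda = tau^2/sigma^2 the ratio of the surface variance to the residual
variance. The sampler works entirely on this marginalized scale — the
subject-level h_i values are never updated — which shrinks the state space
and removes the strong h/hyperparameter coupling. Per iteration the blocks
are:

1. (probit only) latent response y*, element-wise truncated-normal Gibbs;
2. beta, a Gibbs draw from its GLS conditional under a flat prior;
3. sigma^2, conjugate inverse-gamma (continuous outcomes);
4. lambda, random-walk Metropolis-Hastings on log lambda;
5. the (r, delta) spike-and-slab pairs, one sweep in random order;
6. (clustered only) the random-intercept variance ratio, MH on the log.

Surface values are recovered after the fact: for each stored state, h at
any set of points is a Gaussian conditional with mean
`lambda K_{new,n} V^{-1} (resp - X beta)` and covariance
`sigma^2 [lambda K_{new,new} - lambda^2 K_{new,n} V^{-1} K_{n,new}]`, with
`V = I + lambda K`. `posterior_h_draws()` implements this; everything in
the summary layer is built on it.

## Priors and their defaults

* `beta`: flat (improper). The GLS conditional is proper whenever X has
  full column rank.
* `sigma^2 ~ Inverse-Gamma(0.001, 0.001)`: weakly informative.
* `lambda ~ Gamma(shape 1, rate 0.1)`: prior mean 10, allowing the surface
  to carry substantially more variance than the noise while keeping a
  proper tail.
* `r_m`: spike-and-slab. With prior inclusion probability `pi = 0.5`
  (configurable per `kmr_priors()`), an included weight gets a
  Uniform(0, 100) slab by default (a gamma slab is available). Posterior
  inclusion probabilities can be sensitive to the slab; re-running with a
  different slab specification is a one-argument sensitivity analysis and
  is recommended practice.
* Random-intercept variance: parameterized as the ratio
  `lambda_b = tau_b^2 / sigma^2` with a Gamma(1, 0.1) prior, mirroring
  lambda. The ratio parameterization keeps the covariance of the working
  response equal to `sigma^2 C(lambda, lambda_b, r)`, so the sigma^2 update
  stays exactly conjugate; an independent inverse-gamma prior on tau_b^2
  itself would break that. `tau_b^2 = lambda_b sigma^2` is what gets
  reported.
* Probit fits fix `sigma^2 = 1`: the latent-normal probit model is only
  identified up to the latent scale.

Exposures are standardized internally by default (disable with
`standardize = FALSE`), which makes the r_m comparable across exposures in
different units; every user-facing quantity is reported on the original
exposure scale.

## Variable selection moves

Component-wise mode sweeps the M components in random order each
iteration. An excluded component proposes a birth (draw r* from the birth
proposal, flip delta to 1); an included one proposes, with probability 1/2
each, a death (r to 0) or a log-scale random walk within the slab. All
moves are accepted by the exact Metropolis-Hastings ratio, including the
proposal densities.

Two numerical choices matter here and were made deliberately:

* **Birth proposal.** Drawing the birth value from the slab prior itself
  is simple (the densities cancel) but mixes essentially never under the
  default slab: Uniform(0, 100) mass sits almost entirely at weights so
  large that the kernel is numerically diagonal, where a newborn component
  cannot improve the fit. Births instead draw from an equal three-part
  mixture — the slab prior, a truncated Exp(rate 2), and a truncated
  Exp(rate 0.25) — whose density enters the MH ratio. The two exponential
  components cover the short-to-moderate length scales where useful
  weights live on standardized exposures; the slab component keeps death
  moves reversible anywhere in the slab.
* **Starting weights.** All components start included with
  `r_start = 0.25/M`. The scaling with M keeps the *total* initial
  bandwidth sum_m r_m fixed; a fixed per-component start would, for large
  M, start the chain in a kernel-collapse region (K approximately the
  identity) where the likelihood is flat in every r_m and the selection
  indicators simply resample their prior.

Hierarchical (grouped) mode treats each declared group as one unit with at
most one active member — groups are meant for highly correlated pollutants
whose members are near-exchangeable proxies, so one representative carries
the group's signal and the within-group conditional PIPs sum to one. Group
moves are birth (activate a uniformly chosen member), death, swap (move
the activity to another member, drawing a fresh weight), and the slab
walk; singleton groups treat swap as a toggle. Ungrouped exposures keep
the component-wise moves.

## Binary outcomes

Probit regression is used for computational reasons: the latent-variable
representation `y* = h + x'beta + e`, `y = 1(y* > 0)`, `e ~ N(0, 1)` lets
the Gaussian machinery run unchanged on y*. The latent vector is sampled
from its full conditional *with h marginalized out*: y* is jointly normal
with precision `(I + lambda K)^{-1}`, so an element-wise Gibbs sweep draws
each y*_i from a truncated normal whose mean couples it to all other
latent values. Truncation (y*_i > 0 iff y_i = 1) is enforced by
inverse-CDF sampling done on the log scale, which stays exact far into the
tails. Probability-scale quantities apply `pnorm(h + x'beta)` per stored
state; `probit_to_logit()` provides the familiar `1.6 * beta` logit-scale
translation with its usual caveat (outcome probabilities not too close to
0 or 1).

## Clustered outcomes

A cluster random intercept `b_i ~ N(0, tau_b^2)` adds
`lambda_b * B` to V, where B is the block indicator of shared cluster
membership. The intercepts themselves are marginalized — only the variance
ratio is sampled (MH on the log scale) — keeping one code path for all
families. Single-cluster data are rejected: tau_b^2 is unidentifiable.

## Gaussian predictive process

For large n the per-iteration Cholesky of an n-by-n matrix dominates.
Supplying `knots` replaces K by its projection
`K_{Z,knots} (K_{knots,knots} + nugget I)^{-1} K_{knots,Z}` onto a set of
K knots chosen by k-means over the standardized exposure space (a
reproducible space-covering choice; a random-subset method is also
available). All likelihood algebra then runs through Woodbury identities
whose solves and log-determinants are K-dimensional. With knots equal to
the distinct exposure rows the projection reproduces the exact kernel, a
property the test suite checks at 1e-6.

## Effect estimands

All estimands are deterministic functionals of the stored draws,
summarized by the posterior mean and an equal-tailed 95% credible
interval:

* **Overall effect**: h with every exposure at quantile q versus every
  exposure at a reference quantile (`overall_effect()`), covariates held
  constant.
* **Single-exposure effects**: move one exposure between its 0.25 and
  0.75 quantiles with the others pinned at a conditioning quantile
  (`single_exposure_effects()`).
* **Interactive effects**: the difference of a single-exposure effect at
  high versus low conditioning quantiles (`interactive_effects()`),
  computed draw-by-draw.
* **Risk differences** (probit): differences of `pnorm(h + x'beta)`
  between two exposure settings at chosen covariate quantiles
  (`risk_difference()`).
* **Cross-sections**: one- and two-dimensional slices of the surface
  (`univariate_cross_section()`, `bivariate_cross_section()`), the latter
  optionally paneled over a third exposure's quantiles to diagnose
  three-way interaction.

Empirical exposure quantiles use the type-7 (linear interpolation)
convention throughout, for both the estimators and the synthetic-data
truth records, so recovered and true contrasts are directly comparable.

Contrasts are computed from *joint* conditional draws over the union of
the points involved, deduplicated, so (i) a contrast of a setting with
itself is exactly zero with zero width, and (ii) contrast uncertainty
reflects the posterior covariance between the two settings rather than two
independent noise draws. Two prediction modes exist: `"full"` draws from
the Gaussian conditional per state (the default; intervals include the
conditional surface uncertainty) and `"mean"` keeps only the per-state
conditional mean (faster, narrower bands; deterministic given the stored
draws). The mode is recorded on the output, and interval widths differ
between modes by construction. Conditional draws are seeded from the
fit's own seed by default, so any summary recomputed from a persisted fit
reproduces the in-memory result bit for bit.

## Diagnostics

`extract_traces()` returns stored traces in the persisted column schema;
`gelman_rubin()` implements the classic (non-rank-normalized) potential
scale reduction factor `sqrt(((L-1)/L W + B/L)/W)`, floored at 1 since
values below 1 arise only from the finite-sample correction when chains
agree essentially perfectly. `posterior_estimates()` tabulates means,
standard deviations and the 2.5/25/50/75/97.5 percent quantiles.

## Synthetic data and what the tests show

The generators are first-class, seeded, pure functions of their
arguments, with truth records that make every estimand computable exactly:

* `kmr_sim_continuous()` (defaults n = 500, M = 7, exchangeable
  correlation 0.3): five active exposures — a saturating plateau term in
  z7 (steeper at low exposure, flattening at high), positive linear terms
  in z1 and z2, negative in z4 and z5, and a z5-by-z7 product
  interaction; z3 and z6 are inert. Covariate effect beta = 1, noise sd 1.
  These choices emulate a strongly identified mixtures study: a nonlinear,
  non-additive surface over correlated exposures with both directions of
  effect represented.
* `kmr_sim_binary()` (defaults n = 200, M = 30, independent exposures):
  latent-scale quadratics `a (z_m^2 - 1)` on z1..z4 with coefficients
  1.0, 0.8, 0.6, 0.6 plus a 0.5 z1 z2 interaction and beta = 0.5 — a
  high-dimensional selection problem with u-shaped (quantile-contrast-
  defeating) exposure-response forms and roughly balanced prevalence.
* `kmr_sim_clustered()` adds `b_i ~ N(0, tau_b^2)` to the continuous
  generator; with tau_b = 0 it reproduces it exactly under the same seed.

`true_contrasts()` evaluates the overall, single-exposure and interactive
contrasts exactly under the truth function at the realized empirical
quantiles, and probit risk differences in closed form via
`pnorm(h_true + beta x)` (the latent noise is exactly standard normal, so
no Monte-Carlo integration is needed).

What passing tests do and do not show: the generators draw (correlated)
Gaussian exposures with homoscedastic noise and a correctly specified
covariate model. Real mixtures data bring skewed and bounded exposure
distributions, detection limits, measurement error, confounding and
missingness, none of which the fixtures emulate — recovery on these
fixtures demonstrates the estimator and sampler are correct, not that any
real analysis is assumption-free.

## Numerical choices

* All covariance solves go through Cholesky factorization; if a factor
  fails, a symmetric-eigenvalue fallback clips eigenvalues below 1e-10.
* The knot kernel carries a 1e-6 nugget by default (configurable within
  (0, 1e-4]).
* MH proposal scales default to 0.25 (log lambda, log lambda_b) and 0.2
  (slab walk on log r); acceptance rates per move type are reported on
  the fit.
* Degenerate inputs fail loudly: constant exposure columns, single
  clusters, all-0/all-1 binary outcomes, missing values, collinear
  covariates under the GLS solve.
* Problem sizes in the test suite are the fixtures' study scales (n = 500
  continuous, n = 200 binary) with 2000-iteration chains, and a bank of
  reduced-scale (n = 200, 1000-iteration) replicates for interval
  coverage; small dense-algebra oracles run at n = 4 to 25.

## Limitations

* One kernel family (component-weighted Gaussian); no categorical
  exposures; no count outcomes.
* Fixed proposal scales — no adaptation; badly scaled problems may need
  manual tuning through `kmr_control()`.
* Hierarchical selection enforces exactly one active member per active
  group; it is a model for near-exchangeable correlated proxies, not for
  groups whose members carry independent signal.
* The probit latent sweep is O(n^2) per iteration after an O(n^3)
  factorization; very large binary studies should use knots.
* Mean-only prediction understates interval widths by construction; the
  full mode is the honest default.
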