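---
title: "Diet composition from foraging point processes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet composition from foraging point processes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietglm)
```

## The generative model

`dietglm` treats a predator's food-habits sample as the outcome of a
thinned, doubly marked Poisson point process. Prey individuals of category
$c$ are scattered over space with an intensity surface $\Lambda_c(s)$
(individuals per unit area); each individual carries two marks, its species
identity and a body mass drawn from a gamma distribution with mean $w_c$
(kg) and coefficient of variation $v_c$, i.e. shape $k_c = v_c^{-2}$ and
scale $\theta_c = w_c v_c^2$. A predator foraging over an area $A$ attacks
and consumes each encountered individual independently with a thinning
probability. The number of category-$c$ individuals consumed in sample $i$
is then Poisson with mean
$\lambda_{ic} = \text{thinning} \times \int_A \Lambda_c(s)\,ds$, and the
consumed biomass is the compound Poisson–gamma (CPG) sum
$Y_{ic} = \sum_{n=1}^{N_{ic}} B_{icn}$.

The CPG distribution is exactly a Tweedie distribution with power parameter
strictly between 1 and 2:

$$\mu_{ic} = \lambda_{ic} k_c \theta_c, \qquad
  p_c = \frac{k_c + 2}{k_c + 1}, \qquad
  \phi_{ic} = \theta_c (k_c + 1)\, \mu_{ic}^{-1/(k_c+1)},$$

with $\operatorname{Var}(Y_{ic}) = \phi_{ic}\mu_{ic}^{p_c}
= \lambda_{ic} k_c (k_c + 1)\theta_c^2$. `cpg_to_tweedie()` and
`tweedie_to_cpg()` implement this correspondence in both directions; the
package's test suite verifies the round trip to $10^{-10}$ relative error
and validates the variance identity against simulated moments. The scale
formula above is the unique form consistent with that variance identity —
we confirmed it numerically against both a Monte-Carlo moment oracle and an
independent Tweedie density implementation before adopting it.

Two boundary cases are deliberate design choices. An empty intensity
($\lambda = 0$) is a degenerate always-zero distribution with no Tweedie
representation ($\mu > 0$ is an invariant), so `cpg_to_tweedie()` refuses
it with a classed error rather than returning a spurious parameter set. And
$p$ is kept strictly interior to $(1, 2)$ with a $10^{-6}$ buffer wherever
it is optimized: the foraging derivation can only produce interior values
($k \in (0, \infty)$), and the series density assumes them.

## The series density

For $y > 0$ the Tweedie density on $1 < p < 2$ is evaluated through its
latent-count series,

$$f(y) = e^{-\lambda} \sum_{n \ge 1} \frac{\lambda^n}{n!}\,
  \mathrm{dgamma}(y;\, n k,\, \theta),$$

summed in log space with adaptive truncation: the summand band starts at
$n = 1$, and the upper limit grows (starting past the index maximizing the
summand) until every observation's tail term is below $10^{-12}$ of its
running sum. At $y = 0$ the density is the discrete mass $e^{-\lambda}$.
A fast path covers the common GLM case of a single shared power. The
suite checks the density normalizes to 1 within $10^{-6}$ across the power
range, matches the empirical CDF of $10^6$ brute-force CPG draws, and
agrees with `mgcv::ldTweedie` to near machine precision. Sampling uses the
exact composition $Y = \text{Gamma}(Nk, \theta)$ given $N \sim
\text{Poisson}(\lambda)$.

All random draws flow through scoped seeds (`withr::with_seed`): a seed
argument makes any generator bit-reproducible without touching the global
RNG state.

## The foraging simulator and the two approximations

`run_foraging_experiment()` replicates the sampling experiment that
motivates the GLM: three prey with bivariate-normal intensity surfaces
(1000 individuals each, mean mass 1.2 kg, mass CV 1 by default), three
disc-shaped foraging sites of distinct sizes, and Bernoulli thinning. Per
(site, species) cell it compares:

1. the *empirical* sampling distribution over replicates;
2. the *centroid Tweedie*, whose $\lambda$ uses the intensity evaluated at
   the site centroid times disc area — ignoring within-site heterogeneity;
3. the *constant-$(\phi, p)$ GLM approximation*, which additionally pools a
   single scale and power across all cells, estimated by pooled maximum
   likelihood with the cell means held fixed
   (`fit_constant_scale_power()`).

Approximations 2 and 3 share their means, so their implied diet
proportions $\mu_c / \sum_{c'} \mu_{c'}$ are identical by construction —
the package asserts this exactly — even though their zero masses and
density shapes differ. The exact expected count integrates the intensity
over the disc (`expected_lambda(method = "quadrature")`, polar-coordinate
adaptive quadrature, relative tolerance $10^{-6}$); empirical per-cell zero
fractions are checked against $e^{-\lambda}$ from this quadrature.

Design choices here: foraging areas are discs (containment and quadrature
are trivial; polygons are out of scope). Each realization places exactly
`n_individuals` points per species (a conditioned total); with 1000
individuals and the default site sizes the binomial-versus-Poisson
difference in the zero mass is far below Monte-Carlo noise at the
replication counts used. The site and prey geometry of
`foraging_demo_config()` (centers, radii, covariances) is the package's own
representative choice: expected counts per cell span ~0.05 to ~30 so that
both the zero mass and the continuous part are exercised. Thinning defaults to 1
in that configuration; sub-unit thinning is exercised in tests. The pooled
$(\phi, p)$ criterion is maximum likelihood (profile grid over $p$ with
$\phi$ profiled out, then Nelder–Mead on $(\log\phi,
\operatorname{logit}(p-1))$, falling back to the grid optimum — flagged —
if the simplex fails); ML is the natural pooling criterion and the
optimizer is verified against a direct grid.

## The GLM engine

`tweedie_glm()` fits the stacked regression
$\log \mu_{ic} = \alpha_i + \sum_k \beta_{kc} x_{ik}$ on long-format
records (one row per sample × category, zeros explicit). The design has
one intercept column per category; covariates are either
category-interacted (one slope per prey) or shared; $\alpha_i$ is handled
by `alpha = "shared"` (absorbed into category intercepts),
`"sample"` (one fixed offset per sample, first sample as reference — the
multinomial-Poisson configuration), or `"covariate"`. Rank deficiency is
detected up front and reported with the offending columns.

Estimation is iterated in three tiers:

- $\beta$ by Fisher scoring (IRLS) with weights $\mu^{2-p}$, with
  step-halving so the Tweedie quasi-deviance never increases; convergence
  requires both a relative deviance change below $10^{-12}$ and a
  stabilized coefficient vector, which drives the quasi-score
  $\sum_i (y_i - \mu_i) x_{ij} / \mu_i^{p-1}$ below $10^{-8}$.
- $\phi$ by maximizing the exact series log-likelihood given $(\beta, p)$,
  bracketed around the Pearson moment estimate (which keeps the latent
  intensity, hence the series truncation length, moderate).
- $p$ either fixed or profiled: a grid $1.05, 1.10, \dots, 1.95$ followed
  by golden-section refinement to $10^{-4}$ between the bracketing
  neighbors of the grid optimum. The reported fit records the profile
  table, and the suite asserts the returned $p$ attains the profile
  maximum.

Exact zeros and 100%-one-prey samples need no special treatment — they are
in the Tweedie support. A category with *no* positive biomass anywhere is
genuine separation: its intercept diverges to $-\infty$. The engine warns,
clamps the linear predictor at $-30$, and reports `NA` standard errors for
that category rather than failing. Wald coefficient covariance is
$\hat\phi\,(X^\top W X)^{-1}$; across 50 simulated replicates the suite
checks 95% Wald intervals cover at a rate inside $[0.90, 0.99]$.

Penalized smoothers are intentionally out of scope: users pass
pre-computed basis columns (e.g. the quadratic spatial basis the spatial
generator emits) as ordinary covariates, keeping the engine a GLM while
still admitting smooth structure. Random effects are likewise out of
scope. Whether to estimate or fix $p$ in an application is left to the
user; the default is profiled ML, and `glance()` reports which was used.

## Composition and uncertainty

Proportions are the softmax of the per-category linear predictors,
$\pi_c = \mu_c / \sum_{c'} \mu_{c'}$. All terms enter $\eta_c$; terms
shared across categories (including $\alpha_i$) cancel algebraically, so
no term-classification logic exists to go wrong. Consequently $\pi$ is
invariant to the identifiability convention (verified by refitting under a
permuted category order) and to $(\hat\phi, \hat p)$ given the means
(exact, by construction).

Standard errors use the delta method on the proportion scale:
$\partial \pi_c / \partial \eta_{c'} = \pi_c(1\{c = c'\} - \pi_{c'})$,
chain-ruled through the design rows and sandwiched with the coefficient
covariance. Whether such softmax uncertainty is best reported on the
proportion scale or back-transformed from the link scale is a genuine
choice; the package defaults to the proportion-scale delta method and also
exposes `se = "link"`, which reports the SE of $\log \pi_c$ and the
asymmetric interval from exponentiating $\pm 1.96$ of it. The suite checks
the delta SE against a 500-draw parametric bootstrap (within 10%), against
the closed-form logistic delta method in the two-category case, and for
the expected $1/\sqrt{n}$ shrinkage on nested datasets.
`composition_curve()` sweeps one covariate with the others held at
user-supplied reference values, defaulting to training means (recorded in
the output's `"at"` attribute).

The total/proportion reparameterization
$\mu \leftrightarrow (\sum_c \mu_c,\ \pi)$ is provided as an exact
bijection (`reparameterize_total()`).

## The multinomial–Poisson transformation

For integer count tables, the multinomial likelihood for composition is
equivalent to a Poisson regression with one free intercept per sample.
`fit_poisson_equivalent()` implements the Poisson route through the same
IRLS machinery with a dedicated Poisson family (variance $\mu$, exact
Poisson deviance — not a Tweedie limit, so the boundary is exact), and
`fit_multinomial()` the closed form
$\hat\pi_c = \sum_i n_{ic} / \sum_{ic} n_{ic}$. Their agreement to
$10^{-6}$ across randomized tables is asserted, as is the score identity
that fitted per-sample totals equal observed totals. A category with zero
counts everywhere is reported as $\hat\pi = 0$ with a boundary flag
(its log-scale effect has no finite standard error) rather than an error.

## Synthetic data: what it emulates, and what it does not

The generators produce the two case-study *shapes* the field works with,
never the actual field data:

- `gen_timeseries_diet()`: a 37-year series (a 1982–2018-style span) with
  an AR(1) covariate (lag-1 correlation 0.6, unit marginal variance), per-
  category log-linear covariate effects, and a fixed per-category sinusoid
  standing in for a smooth decadal trend.
- `gen_spatial_diet()`: uniform sample locations on the unit square with
  per-category intensity surfaces built from Gaussian bumps. With the
  default single bump per category the log surface is exactly quadratic,
  so a GLM given the quadratic coordinate basis is correctly specified —
  that configuration is used for end-to-end recovery checks (mean absolute
  proportion error under 0.10 at 400 sites; observed ≈ 0.02). More bumps
  give surfaces the basis can only approximate.
- `gen_glm_dataset()`: data simulated exactly from the fitted model, for
  calibration experiments.

Every generator takes a mandatory seed and emits a truth sidecar (the
generating coefficients and the true proportion at every design point), so
recovery tests never re-derive truth from code internals; `write_diet_csv()`
stores it as JSON next to the CSV. Default responses are continuous
biomass; real bill-load or metabarcoding responses may be counts or
frequencies of occurrence, and the generic generator also supports integer
responses via the Poisson limit of small `phi` — interpretation of real
response types is the analyst's responsibility.

Passing tests on these generators demonstrates internal correctness and
statistical calibration *under the generating model*: independent samples,
a correctly specified linear predictor, constant $(\phi, p)$, no
overdispersion beyond Tweedie, no spatial or serial residual correlation.
Real diet data violate several of these (satiation induces
between-category covariance; metabarcoding adds compositional read-depth
artifacts), and the tests say nothing about robustness to those
violations.

## Problem sizes and numerical tolerances

The shipped verification suite uses $10^6$-draw Monte-Carlo oracles for
moment checks (tolerance three Monte-Carlo standard errors), 200
replicates for the foraging experiment, 50 replicates of $n = 500$ samples
for coefficient recovery and coverage, 500 bootstrap draws for the SE
comparison, and 400 sites for spatial recovery — sizes at which every
sampling-error tolerance above is comfortably resolved. Parameter-exactness
assertions (round trips, normalization, softmax identities) use absolute
tolerances between $10^{-14}$ and $10^{-6}$ as stated throughout this
vignette. `scripts/acceptance.R` recomputes the same quantities from a
single command-line seed.

## Known limitations

- No random effects or correlated residuals; between-category covariance
  from satiation or multispecies functional responses is not modelled.
- The power parameter is assumed common to all categories when fitting
  (the GLM approximation); the simulator quantifies, but the fitter does
  not correct, the error this introduces.
- Smoothing-parameter selection, penalized splines, and map rendering are
  out of scope; spatial structure enters only through user bases.
- Wald/delta uncertainty is first-order; simultaneous bands are not
  provided.
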