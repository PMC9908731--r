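---
title: "Multi-year Diversity-Interactions mixed models with dimix"
author: "dimix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-year Diversity-Interactions mixed models with dimix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimix)
```

## The model

Diversity-Interactions (DI) models describe an ecosystem function $y$
(for example, grams of weed biomass harvested from a plot in a growing
season) as a function of the *proportions* $P_1,\dots,P_s$ of the $s$
species present, with $\sum_i P_i = 1$:

$$
y \;=\; \underbrace{\sum_{i=1}^{s} \beta_i P_i}_{\text{identities}}
 \;+\; \underbrace{\textstyle\sum_{i<j} \delta_{ij} P_i P_j}_{\text{interactions}}
 \;+\; \text{design structures} \;+\; \varepsilon .
$$

The identity effect $\beta_i$ is the expected monoculture response of
species $i$; products of proportions carry the pairwise interactions.
When $s$ is large the $\binom{s}{2}$ free $\delta_{ij}$ are neither
estimable nor interpretable, so the interaction surface is
reparameterized. `dimix` implements the standard ladder of structures,
from most to least parsimonious:

* **identity** — no interactions;
* **average** — a single coefficient on $\sum_{i<j} P_iP_j$;
* **fg** — one coefficient per within-functional-group pair sum and one
  per between-group pair sum ($T + \binom{T}{2}$ coefficients for $T$
  groups);
* **additive** — species $i$ contributes a constant $\lambda_i$ to any
  pair it joins; the design column for species $i$ is
  $P_i(1 - P_i) = \sum_{j\neq i} P_iP_j$ (the closed form is used, and
  its equivalence to the explicit pair sum is a tested property);
* **full** — one coefficient per pair.

These column spaces are strictly nested
(identity $\subset$ average $\subset$ fg $\subset$ full), which is what
makes sequential likelihood-ratio comparison meaningful; the nesting is
verified by projection in the test suite.

### Repeated measures and the year-lagged proportions

With $K$ years of repeated measures on each plot, every coefficient is
year-specific by default (`di_fixed(..., by_year = TRUE)`). The
proportions driving year $k$ are the *planted* proportions when $k=1$
and the *realized* (measured end-of-season) proportions of year $k-1$
when $k>1$; `lag_proportions()` rewrites a dataset to this convention.

### Treatment and covariate crossings

A spatial planting-pattern treatment (aggregated conspecific patches vs
dispersed individuals) applies only to mixture plots, so it cannot have
a main effect: monocultures have no level of it. `dimix` follows the
interaction-only coding: treatment-crossed copies of the interaction
columns are zero on rows of other levels, and monoculture rows are zero
in every copy because their interaction columns already vanish. A
proportion-derived covariate (for example legume percentage,
$\sum_{i \in \text{legumes}} P_i$) can scale an interaction block
elementwise; it is applied uniformly to all columns of the block it
multiplies.

### Random pairwise interactions indexed by pair and year

The distinctive component is a lack-of-fit term for the interaction
surface: random effects $d_{ijk}$ indexed by species *pair* $(i,j)$ and
year $k$, not by a plot-level factor. The random design $Z$ has one
column per pair and active year holding $P_{ik}P_{jk}$ on rows of year
$k$ (pair-major, year-minor column order); with 16 species, 170 plots
and 3 years it is a $510 \times 360$ matrix. All pairs share one
variance per year, $d_{ijk} \sim N(0, \sigma_k^2)$, so each active year
costs a single parameter. Because a pair's effect is shared by *every*
plot containing that pair, the marginal covariance
$V = ZGZ' + R$ is not block-diagonal by plot — this is exactly why
standard grouped-random-effect interfaces cannot fit the model directly
and the likelihood is maximized by the package's own engine.

Optionally the per-pair year block $M$ can carry year-to-year
covariances (`di_gstruct(year_cov = TRUE)`), parameterized through its
Cholesky factor with the diagonal floored at zero.

### Residual covariance

$R$ is block diagonal with one $K \times K$ block per plot:
compound symmetry (variance $v$, covariance $c$, positive-definite for
$-v/(K-1) < c < v$), AR(1) ($v$, $\rho$), or unstructured (Cholesky
parameterized). Blocks may be pooled, differ between monocultures and
mixtures, or differ across functional-group monocultures with a common
mixture block (`fgmono`; with four groups that is five distinct blocks).
Any block type combines with any grouping. Plots with missing years
receive the corresponding sub-block.

## Estimation

For given variance parameters, $\beta$ is profiled out by generalized
least squares through one Cholesky factorization per evaluation (no
explicit inverses). The engine whitens each plot block by the factor of
its $R$ block and handles the $q$ active random columns through the
low-rank identity
$(I + UU')^{-1} = I - U(I_q + U'U)^{-1}U'$, so an evaluation costs one
$q \times q$ factorization rather than an $n \times n$ one. With CS or
AR(1) residual blocks a global variance scale is additionally profiled
analytically, leaving only correlations, variance ratios and the yearly
random-interaction variance ratios to the numerical optimizer.

Numerical choices that matter:

* $\sigma_k^2$ is optimized on its natural scale with a floor at zero
  (L-BFGS-B bound), so the boundary value $0$ is attainable exactly —
  required for the boundary likelihood-ratio test below. Correlations
  use tanh/logistic transforms onto their open domains; unstructured
  blocks use log-diagonal Cholesky factors.
* Gradients are bound-aware finite differences (central where possible,
  forward at an active bound).
* Starting values come from per-group moments of OLS residuals; yearly
  random-interaction variances start at 10% of the residual variance.
  On failure the fit restarts with variance starts inflated tenfold, up
  to `dimix_control(restarts = )` times; non-convergence is reported,
  never silent.
* Stopping: L-BFGS-B with `factr = 1e7` (relative criterion change
  around $10^{-9}$). Fits are deterministic given the data.

The REML and ML criteria and the GLS solution are verified in the test
suite against an explicit dense multivariate-normal density on small
instances, and whole fits are cross-checked against `nlme::gls`
(CS, no random effects) and `lme4::lmer` (via the exact
reparameterization plot-intercept + pair-slope $=$ CS with $c>0$ plus
one-year pair effects, on data where every row touches at most one
pair).

## Inference and model selection

Adding the year-$k$ random interactions tests
$H_0\!: \sigma_k^2 = 0$, a parameter on the boundary of its space. The
likelihood-ratio statistic there follows the 50:50 mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ rather than $\chi^2_1$, so
`di_lrt(..., boundary = TRUE)` halves the $\chi^2_1$ upper-tail
p-value (and refuses to do so for df $\neq$ 1). Fixed-effect
comparisons must use ML fits; variance-structure comparisons must use
REML fits with identical fixed effects — both are enforced, not
advisory.

`di_select()` runs the four-step workflow: (1) fixed structure by ML
under a pooled unstructured baseline; (2) residual block type and
grouping by REML; (3) fixed structure re-checked under the chosen
residual structure, then treatment and covariate crossings by ML;
(4) yearly random interactions by REML with halved p-values, activating
exactly the significant years. Every comparison lands in an auditable
trace. Two menu pairs are not nested in each other and are resolved by
documented tie-breaks: `fg` vs `additive` (both compared against
`average`; if both improve, the smaller $-2\log L$ wins) and CS vs
AR(1) (equal parameter count; smaller $-2\log L$ wins before the
UN-vs-winner test). Candidates that fail to converge are treated as
not selected and logged. The default $\alpha$ is 0.05 throughout.

## The simulation study engine

`design_a()` rebuilds the 206-plot, nine-species, three-functional-group
study design: every species twice in monoculture, every pair twice at
50:50, and 48/36/24/8 equal-proportion plots of richness 3/4/6/9. The
printed description fixes only those counts, so the package chooses the
higher-richness community compositions itself, using balanced
constructions (partitions into triples for richness 3 and — via
complements — richness 6; cyclic shifts of base quadruples for
richness 4) so that every species appears equally often at every
richness level. `space_design()` likewise allocates its 170 plots as
16 monocultures + 64 two-species + 48 four-species + 42 eight-species
across five blocks; the per-richness split is this package's documented
choice where only the total and the composition rules are fixed.

`simulate_response()` draws from the functional-group model with
year-specific coefficients plus pair-by-year random interactions
($d_{ijk}$ drawn once per pair-year and *shared across plots*) and
compound-symmetry residuals with correlation 0.5 (covariance half the
variance). Residual standard deviations of 100–300 and
random-interaction standard deviations of 0–2500 are the study's grid;
`di_sim_effects()` supplies the built-in identity and interaction
values on a realistic weed-biomass scale (roughly 1400–3000 g per plot).
The exact values are immaterial for the variance-component tests: REML
statistics are invariant to the mean as long as the fitted fixed model
contains it, and the test suite checks this invariance by rerunning the
tests with a different effect set under identical noise seeds.

What the generator does *not* emulate: realized-proportion dynamics
(proportions are replicated across years), non-normal random effects,
spatially correlated residuals, and unbalanced or missing plot-years.
Passing tests therefore demonstrate correctness of the estimator and
test machinery under the stated model, not robustness to those
departures.

`run_power_setting()` tallies, per simulated dataset, how many of the
$K$ yearly boundary tests are significant; with $\sigma_d = 0$ it
reports the family-level type-I error (at least one significant year),
otherwise the power to flag all years. `run_structure_selection()`
reports how often each fixed structure wins the sequential ML
comparison. Desk-scale runs in the tests and the acceptance script use
200–300 replicates per setting (binomial Monte-Carlo standard errors
are reported alongside every proportion); a full-scale study would use
1000.

## Known limitations and honest behavior of the tests

* The halved-$\chi^2_1$ boundary test is calibrated *per test*: on this
  design its measured size tracks the nominal 5% closely, and the
  zero-boundary estimate occurs in about half of null fits, as the
  mixture predicts. Across three yearly tests the family-level
  false-positive rate is therefore close to $1-(1-0.05)^3 \approx 0.14$
  — no family-wise correction is applied, by design. Implementations
  built on unbounded linear-covariance parameterizations whose
  optimizers stall or require inflated restarts near $\sigma^2 = 0$
  deflate the statistic and can appear several times more conservative
  (with correspondingly lower power when the random-interaction and
  residual scales are close); the bounded, profiled engine here does
  not reproduce that behavior, and its numbers should be read as the
  calibrated reference.
* ML fixed-structure comparisons at large df (functional group vs full
  pairwise adds 90 parameters on the nine-species design) are
  anticonservative in finite samples, which is why the full-pairwise
  structure is selected in a substantial minority of null datasets.
* Dense linear algebra assumes a few thousand observations at most;
  there are no sparse solvers, Bayesian machinery, or small-sample
  denominator-df corrections (Satterthwaite/Kenward–Roger).
* Predictions are fixed-effects only (at the average block level when
  no block is given) and should be restricted to compositions the
  design supports; columns dropped as aliased are reported
  non-estimable and excluded with a warning.

## A short session

```{r example, eval = FALSE}
d <- design_a(seed = 1)
eff <- di_sim_effects(attr(d, "pool"), K = 3)
d <- simulate_response(d, eff, sd_resid = 100, sd_pair = 1500, seed = 7)

fit0 <- dimix(d, di_fixed("fg"), di_rstruct("cs"), method = "REML")
yt <- test_yearly_interactions(d, di_fixed("fg"), di_rstruct("cs"))
yt

fit <- dimix(d, di_fixed("fg"), di_rstruct("cs"),
             di_gstruct(years = yt$significant_years), method = "REML")
summary(fit)
head(blups(fit))
```
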