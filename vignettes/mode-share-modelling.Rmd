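---
title: "Modelling urban active-travel mode shares: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling urban active-travel mode shares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

City-level data on walking and cycling report, for each city and year, the
distance travelled and the number of trips by mode (walk, cycle,
car/motorcycle, public transit), split into travel within the city boundary
and, for a minority of cities, in- and out-bound travel crossing the
boundary. The questions the package addresses are (i) how city-level
conditions — density, bikeway provision, terrain, climate — and national
conditions — fuel prices, income, demography — relate to the share of
travel made on foot or by bicycle, and (ii) what a coordinated improvement
in bicycle infrastructure would plausibly do to motorized travel, transport
CO2, and population health.

# Data contract and derived quantities

Effective annual volumes count within-boundary travel in full and 50% of
in/out-bound travel, the convention used in city greenhouse-gas accounting
for boundary-crossing trips. Cities that do not report in/out-bound travel
(a legal state, roughly 70% of cities) contribute within-boundary volumes
only.

Two denominators coexist deliberately:

* the **regression** share used as the model outcome excludes public
  transit: `walk / (walk + cycle + car_moto)` in effective km. The
  substitution of policy interest is between active travel and private
  motor vehicles, and walking or cycling instead of riding transit delivers
  far smaller externality gains;
* **descriptive** shares include transit, for comparability with ordinary
  mode-share statistics; they are computed for both km and trips.

Pooled descriptive statistics aggregate summed effective volumes across
cities — i.e. cities are weighted by the distance travelled in them — not
by averaging city-level shares.

Covariates enter the design matrix as: natural log of population density;
bikeway provision `B` = km of bicycle facility per 100 km of road; a
nonnegative terrain-ruggedness index (treated as an abstract index; the
package imposes no particular metric); minimum and maximum monthly mean
temperature; the **square of the raw minimum temperature**; and annual
precipitation. The square is formed on the raw Celsius scale *before*
standardization — squaring an already-standardized column would relocate
the curvature of the temperature response. Every covariate is then
standardized against the pooled global sample (one worldwide mean and SD
per covariate, kept in a registry), because the reported "one-SD" effects
compare cities across countries; per-country standardization would make
such comparisons incoherent. Country covariates (gasoline price, log GDP
per capita, dependency ratio) are standardized across countries, each
country counted once rather than once per city, so that "one SD of
gasoline price" refers to cross-country variation.

Cities with `road_km = 0` (provision undefined) or an all-zero regression
denominator (beta likelihood undefined) are excluded from fitting, with
logged counts; they remain in descriptive outputs. Shares exactly at 0 or
1 are compressed into the open interval with the sample-size-aware map
`y' = (y(n - 1) + 0.5)/n`, applied only to boundary values
(`shrink_boundary()`).

# The hierarchical beta regression

For outcome share $y_i \in (0,1)$ of city $i$ in country $j(i)$:

$$y_i \sim \mathrm{Beta}(\mu_i \phi, (1 - \mu_i)\phi), \qquad
\operatorname{logit}(\mu_i) = \alpha_{j(i)} + \sum_k \beta_{j(i),k} x_{ik}$$

$$\alpha_j \sim \mathrm N\!\big(\alpha_0 + \textstyle\sum_m \delta_m z_{jm},\ \sigma_\alpha\big), \qquad
\beta_{jk} \sim \mathrm N\!\big(\gamma_{0k} + \textstyle\sum_{m \in \mathcal M} \gamma_{1km} z_{jm},\ \tau_k\big)$$

The mean–precision parameterization keeps the outcome on (0, 1) with
$\mathrm{Var}(y) = \mu(1-\mu)/(1+\phi)$. Every city-level slope varies by
country, and its country-specific value is moderated by national
covariates; by default only log GDP per capita moderates
($\mathcal M = \{\texttt{ln\_gdp\_pc}\}$), with the other country
covariates entering as main effects on the intercept. Walk and cycle
shares are fitted as two fully separate models; nothing is shared between
the outcomes, and the synthetic generator mirrors that.

Priors (weakly informative on the logit scale, all overridable in
`model_spec()`): $\mathrm N(0, 2)$ on $\alpha_0$ and $\delta$,
$\mathrm N(0, 1)$ on $\gamma_0$ and $\gamma_1$, half-$\mathrm N(0, 1)$ on
$\tau_k$ and $\sigma_\alpha$, Exponential(0.1) on $\phi$. Precision is
global: there is no evidence structure in the data contract to support
country-varying dispersion, and a single $\phi$ is the simplest adequate
choice. Cities are unweighted in the likelihood — the city is the unit of
analysis; distance-weighting belongs to the descriptive layer only.

## Sampling and convergence

Sampling is by Gibbs/Metropolis conditional updates (JAGS). The country
level uses the **centered** parameterization. With conditional samplers
the centered form makes every hyper-mean ($\gamma_0$, $\gamma_1$,
$\delta$, $\alpha_0$) a conjugate normal update given the country-level
parameters, and in benchmarking at the package's recovery problem size it
cut wall time by an order of magnitude while removing the severe
autocorrelation the non-centered form produced in $\delta$ (a non-centered
scheme is the right call for gradient-based samplers, which this package
does not use). The cost is slower mixing of $\tau_k$ when the truth is
near zero (the usual funnel); defaults therefore run long, thinned chains:
2 chains, 1500 adaptation + 2500 burn-in iterations, 500 kept draws per
chain at thinning 10.

Convergence is gated, not advisory: split-chain potential scale reduction
is computed for every hyperparameter and the fit aborts above 1.05;
effective sample sizes below 100 raise a warning. Chains are seeded
deterministically from the spec seed, so identical (data, spec, seed)
triples reproduce identical draws.

# Effects on the percentage-point scale

A covariate's effect in country $j$ is the change in predicted share when
it moves from the reference profile (all standardized covariates at 0 —
the pooled mean city — with the country's own intercept) to +1 pooled SD:
$100\,[\operatorname{logit}^{-1}(\eta_1) - \operatorname{logit}^{-1}(\eta_0)]$
percentage points, computed per posterior draw. The alternative of
averaging effects over the observed covariate profiles was considered and
left as future configuration; the reference profile keeps the headline
numbers interpretable and is what "effect in the median country" suggests.
The **median-country** effect takes the cross-country median within each
draw and then summarizes over draws; it refers to the median of the effect
distribution, not to any particular country. Minimum temperature is
perturbed on the raw scale (+1 SD in °C) and both its linear and squared
columns are moved coherently through the registry.

Moderation is reported two ways, matching how such results are usually
presented: the model's own $\gamma_{1k}$ posterior, and a descriptive
unweighted least-squares regression of posterior-mean country effects on
the standardized moderator with its 95% confidence band. With exactly two
countries the descriptive regression has zero residual degrees of freedom
and is flagged degenerate rather than reported.

# The infrastructure scenario engine

A scenario raises every city's bikeway provision to a floor $B^*$:
counterfactual provision is $\max(B, B^*)$, so cities already above the
floor do not change. Per posterior draw:

1. the B column is re-standardized under the floor using the **factual
   registry** — coefficients were estimated on the factual scale, so the
   counterfactual city is measured on that same scale;
2. both outcomes' linear predictors are re-evaluated and share changes
   computed;
3. added active km = share change × the city's baseline
   regression-denominator km. Total personal travel is held fixed; the
   scenario reallocates it between modes;
4. displaced motorized km = $d_{walk}\,\Delta\mathrm{km}_{walk} +
   d_{cycle}\,\Delta\mathrm{km}_{cycle}$ (central ratios 1:1; literature
   ranges 1.0–3.1 and 0.8–2.1 respectively), split across car/motorcycle
   and transit in proportion to their baseline km. Ratios other than 1
   deliberately break km conservation — they are honored literally;
5. only the car/motorcycle portion saves CO2, and the percent reduction is
   relative to baseline car/motorcycle emissions — displacing transit
   travel is counted as displaced km but not as an emission saving;
6. health benefit = per-km dollar multipliers on added walking and cycling
   km. The shipped multipliers (0.50 and 0.25 USD/km) and the emission
   factor (170 g CO2/km) are **documented placeholders**: defensible
   orders of magnitude, configurable per run, and not calibrated to any
   published valuation. Percent CO2 reductions are invariant to the
   emission factor whenever it is a single global constant.

Displaced km are capped at each city's baseline motorized km (the cap
count is logged; disable with `cap_displacement = FALSE`). Uncertainty
intervals are equal-tailed 2.5/97.5% quantiles across draws of the
aggregate, carrying coefficient uncertainty only; posterior-predictive
beta noise is available in `posterior_predict()` but excluded from
scenario intervals by default since the aggregates average over thousands
of cities. Reported new-construction km are deterministic in the data:
$\sum_i \max(0, B^*/100 \cdot \mathrm{road}_i - \mathrm{bikeway}_i)$.

# The synthetic generator

`truth_config()` + `generate_countries()` + `generate_cities()` draw
datasets from exactly the assumed data-generating process with known
parameters. Default conditions emulate the real study population's
structure: 121 countries × 96 cities; walk regression shares of a few
percent (logit intercept −3.6) and cycle shares around one percent
(−4.4); precisions 50 and 30; between-country slope SDs 0.15; a positive
income moderation of the density slope; and ~30.1% of cities reporting
in/out-bound travel. Covariates are drawn from right-skewed families that
match real-world shapes — log-normal density, half-normal terrain, normal
temperatures, gamma precipitation, zero-inflated gamma provision truncated
to [0, 100] — with one master seed and deterministic per-stage substreams.

Walk and cycle shares are drawn independently per outcome; joint draws
with walk + cycle > 1 are rejected and redrawn (count logged), preserving
the marginal models approximately while keeping records physically valid.
Drawn shares are then converted into volumes: total regression-denominator
km allocated by the shares, transit added through a separate descriptive
share, trips derived from mode-typical trip lengths with noise, and the
in/out-bound split constructed so that the 50% rule reconstructs the drawn
shares exactly.

What the generator does *not* emulate — and therefore what passing
recovery tests cannot certify about real data: spatial correlation between
nearby cities, measurement error and privacy noise in the travel volumes,
smartphone-penetration bias, covariate measurement artifacts, and any
misspecification of the beta/logit link itself. Recovery tests certify the
estimator, not the data.

Fixture presets `tiny` (3 × 5), `small` (10 × 20), and `recovery` (30 ×
40) write byte-stable CSV pairs plus a JSON ground-truth sidecar. The
recovery preset is the package's standard parameter-recovery condition:
large enough that 95% credible intervals are informative, small enough
that a full fit runs in minutes on one CPU; the companion degenerate-
hierarchy check runs at 20 × 30. At the recovery size the walk-share fit
covers the slope hyper-means' truth for all seven city covariates and the
density moderation coefficient.

# Numerical choices and edge cases

* `beta_logpdf()` is written directly from the log-gamma form of the
  mean–precision kernel; tests verify it against quadrature normalization
  and the standard shape parameterization.
* Degenerate designs fail loudly: zero-SD covariates, orphan country ids,
  boundary shares (with row indices), unknown modes, empty inputs.
* Effect-table ties are broken lexicographically by covariate name.
* Single-country designs keep country covariates on their raw scale (an
  SD across one country is undefined); the registry records SD 1.
* All quantile summaries are equal-tailed; a one-draw posterior yields
  degenerate (lower = mean = upper) intervals rather than an error.

# Known limitations

Associations, not causes: the model is a hierarchical regression on
observational aggregates, and the scenario engine propagates those
associations as if they were intervention effects — the standard, clearly
labelled limitation of this design. The engine also excludes nonlinear
uptake dynamics (safety-in-numbers feedbacks), safety and air-quality
co-benefits, and any extrapolation beyond the cities present in the data.
The health and emission constants are placeholders by design; absolute
dollar and tonne figures should only be quoted after supplying locally
appropriate values, while share shifts and percent CO2 reductions are
robust to them.
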