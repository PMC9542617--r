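---
title: "Spatially varying coefficient trend models for count-circle surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially varying coefficient trend models for count-circle surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Volunteer butterfly counts (and similar programmes such as the Christmas
Bird Count) tally every individual of a species seen inside a fixed circle
— here a 15-mile (~24 km) diameter circle — on one or more days each summer,
and record the *party hours* spent searching. Counts from such programmes
carry three entangled signals: where the species is abundant, how hard
people looked, and how abundance is changing. `svctrend` separates them with
a two-stage Bayesian analysis and ships a synthetic-data generator so that
every stage can be checked against known ground truth.

## Stage one: the negative-binomial SVC trend model

Counts `y` from circle *k* in grid cell *i* and year *t* are modelled as
negative binomial with size (overdispersion) parameter $\Phi$ and mean
$\mu_{i,t}$ given by

$$\log \mu = \alpha_i + \epsilon_i \log E_{i,k,t} + \tau_i T_t +
  \gamma_{i,t} + \kappa_k .$$

* $\alpha_i$ — cell intercept. Because effort enters as $\log E$ and the
  year covariate is coded with $\max(T) = 0$ (earlier years are negative
  integers), $\exp(\alpha_i)$ is the expected count at one party-hour of
  effort in the final year.
* $\epsilon_i$ — cell-specific effort exponent: the power-function
  correction $\mu \propto E^{\epsilon_i}$ accommodates saturating
  ($\epsilon < 1$), linear ($\epsilon \approx 1$) or accelerating effort
  response.
* $\tau_i$ — cell-specific log-linear trend; `100 (e^{\tau_i} - 1)` is the
  trend in %/yr.
* $\gamma_{i,t}$ — exchangeable cell-year wobble not captured by the
  log-linear trend; $\kappa_k$ — exchangeable circle effect (habitat,
  observer skill).

$\alpha$, $\epsilon$ and $\tau$ are intrinsic CAR (iCAR) random fields over
the occupied-cell contiguity graph: each cell's value is conditionally
centred on the mean of its neighbours. Each field is written as its mean
(`alpha_center` etc.) plus a constrained deviation that sums to zero within
every connected component.

### Structure-matrix scaling and priors

The iCAR precision is $\sigma_f^{-2} Q$ with $Q = D - A$. Before use, $Q$ is
rescaled per connected component so that the geometric mean of the
constrained marginal variances (the diagonal of the generalized inverse of
$Q$ under the sum-to-zero constraint) equals one (`scale_icar()`). After
scaling, $\sigma_f$ means the same thing on every graph, so one penalized
complexity (PC) prior — an exponential on $\sigma_f$ with
$P(\sigma_f > 1) = 0.01$, i.e. rate $\lambda = -\log(0.01) = 4.605$ — is
used for all three fields and for the $\gamma$ and $\kappa$ standard
deviations. Isolated cells, where the iCAR density is undefined, are given
an independent standard-normal effect, consistent with the unit scaling of
their connected neighbours; they are flagged in the structure object.

For the NB size $\Phi$ the PC-prior idea (penalize the distance from the
Poisson base model) is applied to the gamma-frailty representation of the
negative binomial: the frailty standard deviation $d = 1/\sqrt{\Phi}$ is the
natural distance scale (the Kullback–Leibler divergence from the base grows
as $d^2/2$), and $d$ receives an exponential prior with rate `l = 7`. The
exact distance convention for this family differs between software
implementations, so a gamma prior on $\Phi$ is available as a sensitivity
fallback (`nb_dispersion_prior(form = "gamma")`).

The default contiguity rule is queen: cells sharing only a corner are 50 km
apart centre-to-centre just like edge-sharing ones, and queen keeps
diagonal chains of occupied cells in one component. Rook is available.

### Inference

`fit_trend()` samples the joint posterior with a Hamiltonian Monte Carlo
sampler written for this model (Rcpp/RcppArmadillo). Design choices that
matter:

* **Exact constraints by parameterization.** Each iCAR field is expanded in
  the spectral basis of its scaled structure matrix restricted to positive
  eigenvalues, so the per-component sum-to-zero constraints hold exactly in
  every draw instead of being imposed by projection. $\gamma$ uses a
  per-cell sum-to-zero basis over years (so the cell intercept absorbs the
  level and $\tau$ the log-linear component), and $\kappa$ a global
  sum-to-zero basis over circles.
* **Interwoven scale updates.** Conditional on the five standard deviations
  and $\Phi$, the coefficient posterior is well-behaved and is updated by
  HMC (jittered trajectories, dual-averaging step size, diagonal mass
  adaptation during warmup). Each standard deviation is then updated by
  univariate slice sampling twice per iteration: once from its sufficient
  conditional given the coefficients, once from its ancillary conditional
  given the whitened coefficients (an interweaving move). This keeps mixing
  healthy whether a field is strongly identified (many observations per
  cell, e.g. $\alpha$) or weakly identified (e.g. $\tau$), where a single
  parameterization develops a funnel. $\Phi$ is slice-sampled from its
  conditional.
* **Decorrelated centers.** Log effort is nearly constant across events and
  $T$ has a non-zero mean, so the three field means are nearly collinear
  with the intercept; the sampler works in the exactly reparameterized
  coordinate $\alpha_0' = \alpha_0 + \epsilon_0 \overline{\log E} +
  \tau_0 \bar{T}$ (unit Jacobian) and transforms back afterwards.
* **Convergence gate.** Split R-hat is computed for every raw coordinate;
  the fit aborts when any monitored scalar (centers, log SDs, $\log \Phi$)
  exceeds 1.05, unless overridden. Defaults are 4 chains of 2000 post-warmup
  draws after 1000 warmup iterations; the two slowest-mixing scales (the
  $\alpha$ and $\epsilon$ field SDs, anti-correlated because log-effort is
  nearly constant) need that length to clear the gate reliably.

`summarize_cells()` reports posterior medians and symmetric 95% credible
intervals per cell (5000 draws by default, resampling with replacement and a
message when fewer are available), the trend transformed draw-wise to %/yr,
and a flag for cells whose interval excludes zero. `pooled_trend()` pools
$\tau_i$ draws across cells with equal weight — by concatenation (the pooled
posterior, whose median and $P(>0)$ are the headline summaries) or by
within-draw averaging (`method = "mean"`, the posterior of the global mean
trend, which is the natural recovery target in simulations) — and accepts
regional cell subsets.

## Stage two: the gamma covariate model

`compute_index()` turns a posterior draw into an annual relative-abundance
index $\omega_{i,t} = \exp(\alpha_i + \tau_i T_t + \gamma_{i,t})$ — the
expected count at one party-hour — and `fit_covariate_model()` explains it
with three cell-year covariates (glyphosate use P, mean annual temperature
Z, cumulative annual precipitation N):

$$\omega_{i,t} \sim \text{Gamma}(\text{mean} = \Omega_{i,t},\,
  \text{shape} = s), \qquad
  \log \Omega_{i,t} = \beta_i + \rho_i P_{i,t} + \zeta_i Z_{i,t} +
  \nu_i N_{i,t},$$

with $\beta, \rho, \zeta, \nu$ iCAR fields on the same scaled graph as
stage one. To propagate stage-one uncertainty the fit is repeated over
replicate index tables built from randomly sampled posterior draws
(`abundance_index_draws()`), and replicate estimates are pooled into
medians and symmetric 95% intervals per cell. Two alternatives exist for
the year term: the default evaluates $\tau_i T_t$ at the coded year; a
`"literal"` mode adds $\tau_i$ as a constant. Both are exposed because the
printed index formula is ambiguous about the year index; the scaled form is
the default since the index is otherwise independent of the year within a
cell apart from $\gamma$.

Choices made where the design was open:

* **Per-replicate fits are penalized MAP + Laplace.** Thousands of full
  MCMC fits are not desk-scale; each replicate is fitted by L-BFGS with
  analytic gradients on the log posterior, followed by one draw from the
  Gaussian Laplace approximation at the mode so that stage-two estimation
  uncertainty also enters the pooled intervals. Replicate failures are
  excluded and reported; more than 5% is an error. The default replicate
  count at desk scale is 200 (configurable up to 5000); the summary table
  reports the Monte-Carlo SE of each median so users can judge sufficiency.
* **Covariates are centred and scaled** over all cell-years by default
  (recorded and invertible): the iCAR slope priors act on comparable scales.
  A raw-scale mode is available.
* **The gamma shape prior** is PC-style by analogy with the rest of the
  model: exponential with rate 4.605 on $1/\sqrt{s}$, i.e.
  $P(1/\sqrt{s} > 1) = 0.01$. This is an assumption, not a reproduction of
  any published choice.
* **Overlap weights are county-area proportions** in
  `glyphosate_to_cells()`, because that convention conserves each county's
  crop-offset total exactly (verified to 1e-9 in tests); pounds are
  converted to kg exactly once, at ingest, and logged.

## The synthetic-data generator

`scenario()` + `simulate_counts()` generate data from exactly the stage-one
model, with known ground truth returned alongside the events, and
`simulate_covariates()` produces covariate tables with the qualitative
features of the real ones (a pesticide ramp that plateaus, a latitudinal
temperature gradient with a warming trend, noisy precipitation). Covariate
effects can be baked into the cell-year term to close the two-stage loop.

Defaults are the emulated survey conditions: a 6×6 grid of 50-km cells, a
15-year series ending 2018 (within the 10–26-year spans of the emulated
programme), an average of 1.21 circles per cell with a maximum of three
(realized as 1 + Binomial(2, 0.105)), party-hour effort drifting upward at
1.2%/yr with lognormal visit noise (sd 0.2), a mean trend
`tau_center = log(1.0136)` (+1.36%/yr), and a near-linear mean effort
exponent (`epsilon_center = 1`). Values the emulated programme does not pin
down were chosen once as field-realistic and are not tuned: 10 party-hours
of base effort, field marginal variances 0.5 / 0.05 / 0.001 for
$\alpha$ / $\epsilon$ / $\tau$ (cell trends spread ±3%/yr around the mean),
`gamma_sd` 0.15, `kappa_sd` 0.3, and NB size $\Phi = 2$ (variance roughly
$\mu + \mu^2/2$, strong but not extreme overdispersion for insect counts).

What the generator does *not* emulate — and hence what passing
parameter-recovery tests do not establish about real data: observer skill
beyond a static circle effect, within-season phenology, preferential siting
of circles, detection distance, species confusion, and spatial covariance
in effort. The generator is a model-faithfulness instrument, not a survey
simulator.

## Numerical choices and degenerate inputs

* Structure-matrix scaling uses a dense eigendecomposition per component;
  the test suite checks it against an independent pseudo-inverse identity
  to 1e-8 for graphs up to 12 cells. Scaling is idempotent.
* Grid membership is half-open (`[xmin, xmax)` in both axes) so a circle on
  a shared edge belongs to exactly one cell — the cell whose interval
  starts at the edge; the grid's outer boundary is closed so no point of
  the extent is orphaned.
* A zero-variance field request yields an exactly zero field; effort must
  be positive (a zero-party-hour record is rejected, not imputed); a
  missing month in the climate summaries is an error, never imputed.
* Fit problem sizes used in the shipped checks (chosen to keep the whole
  suite at desk scale): 6×6 grid, 15 years for recovery studies, with
  2 chains × 1200/1200 iterations; 50 replicates for second-stage recovery
  checks.

## Known limitations

* The HMC backend is exact only in the MCMC limit; short chains rely on the
  R-hat gate. For very large graphs (hundreds of cells) the dense spectral
  basis becomes the bottleneck; a sparse-solver backend would be the next
  step.
* The second stage treats each replicate's index table as gamma-distributed
  given covariates; it does not model the sampling covariance between
  cell-years within a replicate.
* `pooled_trend()`'s concatenated posterior mixes cross-cell spread with
  estimation uncertainty by construction (it is a descriptive pooled
  distribution, not an estimator of the mean trend); use
  `method = "mean"` when an estimator is wanted.
* No model comparison (WAIC/DIC) is provided; the package fits one trend
  model, and the covariate model is main-effects-only and contemporaneous.
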