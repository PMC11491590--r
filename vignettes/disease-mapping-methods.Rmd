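---
title: "Methods: Leroux CAR smoothing and uncertainty encodings in caratlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Leroux CAR smoothing and uncertainty encodings in caratlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caratlas)
```

# The problem

Small-area cancer statistics — incidence relative to the national rate, or
mortality in excess of the background population hazard — are published for
thousands of administrative areas, most with small populations. The raw
area-level ratios are extremely noisy, so atlases smooth them with Bayesian
spatial models and, crucially, publish the posterior uncertainty alongside
the point estimates. `caratlas` implements that stack end to end: spatial
graph construction, the two likelihoods, an MCMC sampler, posterior
summaries, and the uncertainty-aware visual encodings. This vignette is the
package's own account of the modelling and design choices.

# Models and prior

## Likelihoods

The **incidence** model treats the observed case count in area $i$ as

$$y_i \sim \text{Poisson}(E_i\, e^{\mu + S_i}),$$

where $E_i > 0$ is the externally age-standardized expected count. When the
$E_i$ are built from national rates, the area-level standardized incidence
ratio $\mathrm{SIR}_i = e^{\mu + S_i}$ equals 1 at the national average,
which keeps the exceedance reference at exactly 1 on the ratio scale.

The **excess mortality** model is a piecewise-constant excess-hazard Poisson
form over follow-up intervals $j$:

$$d_{ij} \sim \text{Poisson}(e_{ij} + t_{ij}\,\lambda_j\, e^{S_i}),$$

with observed deaths $d_{ij}$, expected background deaths $e_{ij}$ from
population life tables, person-time $t_{ij}$, and interval baselines
$\lambda_j > 0$ absorbing the national average excess hazard, so the excess
hazard ratio is $\mathrm{EHR}_i = e^{S_i}$ with reference 1. This
proportional-excess-hazards form is the simplest member of the relative
survival model family that yields an area-level ratio against a national
reference; richer relative-survival likelihoods are out of scope.

An assumption shared by both likelihoods is conditional independence of
counts given the spatial field, and no covariates: all residual spatial
structure is carried by $S$.

## The Leroux CAR prior

The spatial effects get a Leroux conditional autoregressive prior,
$S \sim N(0, Q^{-1})$ with

$$Q = \frac{1}{\sigma^2}\left[\rho (D - W) + (1-\rho) I\right],$$

where $W$ is the binary adjacency matrix of the region graph and $D$ its
degree matrix. The mixing parameter $\rho$ interpolates between independent
effects ($\rho = 0$: $n$ iid $N(0, \sigma^2)$ variables) and the intrinsic
autoregression ($\rho \to 1$). We restrict $\rho \in [0, 1)$ so the joint
prior is proper without a sum-to-zero constraint; this avoids special-casing
the intrinsic limit and keeps disconnected components and isolated areas
(real maps have islands) well-defined — an isolated area's conditional prior
is simply $N(0, \sigma^2/(1-\rho))$. The precision is stored sparse
(`Matrix`), since realistic maps have ~2000 areas with ~6 neighbors each.

For polygon input the package derives **queen contiguity**: two areas are
neighbors iff their polygons share at least one boundary point. This
maximizes connectivity for irregular administrative polygons. Detection uses
shared vertices plus vertex-on-segment checks with a bounding-box prefilter,
which is exact for administrative boundary files (touching polygons share
vertices there); purely set-theoretic boundary crossings at non-vertex
points would be missed, a documented limitation. Distance-based and
row-standardized weights are deliberately not offered.

## Hyperpriors

The source models leave hyperpriors unstated, so the package uses standard
weakly informative proper choices: $\sigma \sim \text{half-Normal}(0, 1)$ on
the spatial standard deviation (ratio-scale effects in disease mapping
rarely exceed a few fold, so $\sigma < 2$ a priori with high probability),
$\rho \sim \text{Uniform}(0, 1)$, and $N(0, 10^2)$ on $\mu$ and each
$\log \lambda_j$. All are configurable via `car_priors()`.

# MCMC

`run_chain()` is a Metropolis-within-Gibbs sampler with a compiled (Rcpp)
core, the standard architecture for CAR models at this scale:

* $S_i$: single-site random-walk Metropolis. The full conditional depends
  only on the $O(\text{degree})$ neighboring terms of the sparse precision,
  so one sweep costs $O(n + |E|)$.
* $\mu$ (or each $\log \lambda_j$): random-walk Metropolis.
* $\log \sigma^2$: random-walk Metropolis. The half-Normal prior on
  $\sigma$ is not conditionally conjugate, so no Gibbs step is available.
* $\text{logit}\,\rho$: random-walk Metropolis. The determinant term
  $\frac12 \log\det[\rho(D-W) + (1-\rho)I] = \frac12\sum_k \log(\rho
  \omega_k + 1 - \rho)$ uses the eigenvalues $\omega_k$ of $D - W$, computed
  once per fit by a dense symmetric eigendecomposition (cheap at the few
  thousand areas this package targets).

Step sizes adapt during burn-in only, in batches of 50 iterations with a
Robbins-Monro-style shrinking log-scale adjustment toward acceptance 0.44,
then stay frozen so the retained chain is a genuine Markov chain. Defaults
are 60 000 iterations, 20 000 burn-in, thinning 20 (2000 retained draws);
the simulation studies in the tests use 20 000/10 000/10, which mixes well
at 100 areas. Initialization is moment-based and always in the domain:
$\mu = \log(\sum y / \sum E)$, $S = 0$, $\rho = 0.5$, $\sigma^2 = 0.1$,
$\lambda_j = \max(10^{-6}, (\sum d - \sum e)/\sum t)$. A non-finite
log-posterior at initialization is an immediate error; acceptance rates
outside $[0.05, 0.95]$ after adaptation are recorded as warnings in the
result's metadata, not errors.

Draws are stored exponentiated (ratio scale) because both the PPD and the
wave plot are defined against the ratio-scale reference of 1; log-scale
views are recomputed on demand. Chains are bit-reproducible given the seed.
`convergence_report()` supplies a per-area effective sample size (Geyer
initial-positive-sequence estimator) and a split-chain potential scale
reduction factor; a constant chain has undefined diagnostics and is
reported flagged rather than erroring. The package intentionally runs a
single chain with split diagnostics; parallel chains and gradient-based
samplers are non-goals.

# Posterior summaries

Per area the package reports the **posterior median** (the atlas point
estimate), **equal-tailed 60% and 80% credible intervals**, the **PPD**
(share of draws above 1), the folded confidence $\max(p, 1-p)$, and a
category. Numerical conventions that matter for reproducibility:

* Quantiles use linear interpolation between order statistics ("type 7",
  R's default). Interval endpoints depend on this rule, so it is part of
  the package contract.
* Intervals are equal-tailed, not HPD: the "probability 0.8 that the true
  value lies in this interval" reading is exact for equal tails even for
  skewed ratio-scale posteriors, and equal-tailed intervals commute with
  the log transform.
* Draws exactly equal to the reference count half toward the PPD, removing
  directional bias in the measure-zero tie case.
* The "likely higher / likely lower / uncertain" categories use PPD cutoffs
  (0.2, 0.8) by default. The source atlas prints no cutoffs; these are
  explicit, configurable package choices.

# Visual encodings

**Wave plot.** Densities of ratio-scale quantities mislead on a linear
axis, so the wave plot estimates the density of $\log(\text{SIR})$ — a
Gaussian kernel estimate with Silverman's rule-of-thumb bandwidth, evaluated
on an even log-scale grid extending 3 bandwidths beyond the draw range —
and relabels the axis with exponentiated values. The default tick set
$\{0.5, 0.75, 1, 1.33, 2\}$ is symmetric as ratios. The overlay glyph shows
the posterior **median** with the 60%/80% bands; where source descriptions
of the overlay waver between mean and median, the median wins for
consistency with the published point estimate. The density integrates to 1
on the log grid (enforced by test), and every tick label equals
$e^{\text{position}}$ at 3-significant-digit formatting.

**V-plot.** Each area is a point at (point estimate, folded confidence).
Folding the exceedance probability makes departures in either direction rise
symmetrically toward the top — the property that motivated replacing the
earlier unfolded scatter, which over-emphasized areas above the average.
The x-axis is logarithmic with ratio labels so $r$ and $1/r$ mirror about 1;
whether the production atlas uses a log or linear axis is not documented,
and the log choice is what makes the mirror symmetry exact.

**Map color and transparency.** Estimates map to a reversed
blue–yellow–red diverging ramp (ColorBrewer-style anchors, configurable)
positioned linearly in log space so the color gradient is consistent
between break-points. Default break-points $(0.5, 2)$ are symmetric in log
space, making $r$ and $1/r$ equally saturated. The mapping is
piecewise-linear anchored at 1 ↦ midpoint, so an estimate of exactly 1
renders as the pale neutral yellow for *any* break-points — the midpoint
was deliberately lightened so the average color reads distinctly. The PPD
drives opacity: with $c = 2|p - 0.5|$, opacity is $\alpha_{\min}$ below
$c_{lo}$, 1 above $c_{hi}$, linear between (defaults
$c_{lo}=0.2, c_{hi}=0.6, \alpha_{\min}=0.1$). Uncertain areas therefore
fade toward the same yellow as the national average — a deliberate
congruence: "indistinguishable from average" and "too uncertain to call"
read the same. The floor $\alpha_{\min} > 0$ keeps faded areas visible.
The exact transfer function and class breaks of the production atlas are
unpublished; these defaults are explicit stand-ins, and the whole encoding
can be toggled off (every $\alpha = 1$), mirroring the atlas's default-on
toggle.

**Estimate overviews.** Group-level summaries (e.g. by city, state,
socioeconomic or remoteness class) as stacked barcode bars of the color
classes — percentages or counts — or as five-number-summary boxplots, all
groups on one shared axis for comparability. Class bins are equal-width on
the color-position scale, so bars and map use the same classes.

All spec objects (wave, V-plot, styles, overview) are plain data and
serialize to JSON; the `render_*` functions are presentation-only ggplot2
wrappers, so every number shown is testable upstream of any drawing code.

# Synthetic scenarios

`scenario_config()` / `simulate_incidence()` / `simulate_survival()`
generate data *from the model family itself* on a rook-adjacency lattice
(rook rather than queen because the closed-form edge count
$r(c-1)+c(r-1)$ makes structural tests exact). Spatial fields are exact
draws from the Leroux prior via dense Cholesky factorization, capped at
2500 areas — fixture scale. Defaults are the package's reference study
conditions: a 10×10 lattice, $\rho = 0.8$, $\sigma^2 = 0.25$, $\mu = 0$,
$E_i \sim U(50, 200)$; survival scenarios use five annual intervals,
baseline excess hazard 0.05/person-year, background hazard
0.02/person-year and 500 person-years per area-interval — registry-scale
magnitudes for a moderately lethal cancer.

Because the generator matches the fitted family, simulation checks verify
*self-consistency*: interval calibration (pooled 80%/60% coverage over 10
replicate fits of the reference scenario, 1000 area-checks), hyperparameter
recovery, and agreement with closed-form oracles (conjugate Gamma–Poisson
limit, prior-only marginal variances, lognormal PPD). What passing does
**not** show: robustness to misspecification — real registry data have
non-Poisson overdispersion, covariate structure, irregular graphs,
suppressed cells and imperfect expected counts, none of which the lattice
scenarios emulate. The generator also makes no attempt at real geography or
population age structure.

# Numerical choices and limitations

* CSV floats are written with 6 significant digits for cross-platform
  diffability; round-trips are exact at that precision and all readers
  reconstruct the package's objects.
* The `rho` determinant uses one dense eigendecomposition per fit
  ($O(n^3)$, seconds at $n \approx 2000$); for much larger maps a sparse
  Cholesky per proposal would be preferable.
* Single-site updates mix slowly when $\rho$ is extreme and expected
  counts are tiny; the diagnostics in `convergence_report()` are the guard.
* The intrinsic CAR ($\rho = 1$) is intentionally excluded.
* The CLI (`inst/cli/caratlas.R`) is a thin wrapper over exported
  functions; it adds no logic of its own.
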