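---
title: "Modelling fruit-availability landscapes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fruit-availability landscapes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitscape)
```

# The problem

Frugivores in tropical forests track a resource that is patchy in space and
strongly episodic in time. When a single tree species is a keystone food —
as the large emergent *Dipteryx oleifera* is on Barro Colorado Island (BCI),
fruiting at the start of the dry season when little else is available — an
agent-based model of animal movement needs a *statistically realistic*
map of when and where fruit is on offer, not a literal census that no field
campaign could provide. fruitscape builds that map by fitting three linked
models to the kinds of data that are actually collectable — partial aerial
surveys, mapped plots, haphazard DBH samples and a handful of long-term
fruit traps — and then composing them into a stochastic, island-scale,
multi-season simulation of daily fruit production per tree.

# The three fitted models

## Spatial distribution: an inhomogeneous Poisson process

Tree positions are treated as a spatial point pattern in a planar window.
The reference model is the homogeneous Poisson process with intensity
$\lambda$ (trees/m²), whose maximum-likelihood estimate is the observed
density $n/|A|$. Because real stem maps reject homogeneity, the package
fits an inhomogeneous model in which the log intensity is linear in a
spatial covariate $Z(s)$:

$$\log \lambda(s) = \alpha + \beta\, Z(s).$$

The covariate itself is built from the *detected* (aerial-survey) trees:
an isotropic Gaussian kernel surface with bandwidth $\sigma$, each point
weighted by its inverse detection probability so the surface estimates
total rather than visible density. Fitting uses Berman–Turner quadrature —
dummy points at the covariate grid cells plus the data points, with
counting weights, passed to a weighted Poisson GLM — which maximizes the
point-process log-likelihood
$\sum_i \log\lambda(s_i) - \int_A \lambda(s)\,ds$ and satisfies the score
identity (fitted expected count = observed count) at the optimum. A
proportional link $\lambda = \beta Z$ is available behind a flag; the
log link is the default because it guarantees a positive intensity and is
the standard covariate formulation.

**Bandwidth selection.** The original analysis states only that $\sigma$
was chosen to optimize the fit. A naive maximized likelihood degenerates as
$\sigma \to 0$ (the covariate spikes at the data points), so the package
uses a leave-one-out cross-validated point-process log-likelihood: at each
data point the covariate is evaluated with that point's own kernel
contribution removed. The criterion is computed on a user-supplied grid of
candidate bandwidths (default 50–400 m, including the published optimum of
172 m) and the full profile is returned for plotting. This is a surrogate
for the unstated original criterion, documented as such, not claimed
identical.

**Goodness of fit.** The qq-plot envelope diagnostic smooths the raw
residual field (kernel intensity estimate of the pattern minus the equally
smoothed fitted intensity, both renormalized by the kernel mass inside the
window at the evaluation cell) at half the covariate bandwidth, takes its
quantiles over grid cells, and compares them with the mean and pointwise
95% band of the same statistic across patterns simulated from the fitted
model (39 simulations give an exact min/max 5% pointwise envelope; 100 is
the conventional default). The residual type is a design choice — the
source analysis does not name its residuals — and self-consistency is
verified by simulation: patterns drawn from a fitted model fall inside
their own envelope in well over 90% of replicates.

## Detection: a logistic model of aerial visibility

Only a fraction of trees are identifiable on aerial photographs, and that
fraction grows with stem diameter. The package fits
$\mathrm{logit}\,p(\text{visible}) = \beta_0 + \beta_1\,\text{DBH}$ by
maximum likelihood when labelled ground-truth exists, with a
likelihood-ratio test of the slope. When only the overall visibility
fraction is known — 14.7% of stems over 200 mm DBH in the BCI survey — the
intercept is calibrated by a one-dimensional root find (tolerance 1e-8 on
the fraction) so the mean detection probability over a reference DBH
sample above 200 mm equals the target, for a configurable slope
(default 0.003 per mm). The published coefficient values themselves are
not machine-readable in the source we derive from, so the printed fraction
is the quantitative anchor.

## Phenology: two crossed-random-effects models

Trap records are summarized per tree-season into three traits: production
(total fruits), peak (count-weighted mean trap day, on a season clock with
day 0 = July 1) and duration (four times the count-weighted SD of trap
days, with an $n-1$ denominator over individual fruits; undefined below
two fruits). Monitored trees are observed every season, so the tree ×
season grid is completed with zero-production rows — omitting the zeros
would bias the production intercept upward.

Two models carry the simulation:

* **Model I (production).** $N_{ij} \sim
  \mathrm{Poisson}(\exp(c_1 + c_2\,\mathrm{dbh}_i + u_i + v_j))$ with
  crossed tree and season random intercepts, fit by Laplace approximation
  (lme4::glmer). DBH is centred and scaled internally for the optimizer and
  the coefficients are reported back on the raw mm scale. The published BCI
  estimates, carried as defaults, are $c_1 = -0.12$,
  $c_2 = 1.50\times10^{-3}$ per mm, $sd_u = 0.49$, $sd_v = 0.87$.
* **Model II (timing).** The day each individual fruit falls,
  $day = c_3 + w_i + z_j + \varepsilon$, fit by REML (lme4::lmer). The
  residual SD is the quantity of scientific interest: it measures the
  within tree-season spread of fall dates, i.e. the duration of the
  fruiting season. Published values: $c_3 = 209.3$ d (late January),
  between-tree 13.31 d, between-season 8.51 d, residual 19.62 d.

This pair replaces a nonlinear Gaussian mixed model of the weekly trap
counts (amplitude and peak varying randomly by tree and season), which is
statistically equivalent in spirit but computationally fragile; it is
deliberately not implemented.

Three descriptive models (one per trait, production delegating to model I;
peak and duration as intercept-only Gaussian crossed-random-effects REML
fits) are kept as separate entry points because both parameterizations are
informative summaries.

**Variance-component tests.** Null values of variance components sit on
the boundary of the parameter space, where the usual $\chi^2$ asymptotics
fail, so p-values come from a parametric bootstrap of the ML
likelihood-ratio statistic: simulate from the fitted null, refit both
models, and report $p = (1 + \#\{LR^* \ge LR_{obs}\})/(n_{boot}+1)$
(default 1000 replicates). For the Gaussian intercept-only models the
bootstrap uses a purpose-built profiled-ML engine: with one or two crossed
random-intercept factors, the marginal likelihood reduces, via the
Woodbury identity on the factor cross-tabulation, to a box-constrained
optimization over one or two variance ratios with $O(q^3)$ cost per
evaluation ($q$ = number of trees + seasons), independent of the number of
fruits. The engine is verified against lme4 ML deviances to 1e-4 in the
test suite; the GLMM components use lme4 refits directly. When the
observed LR statistic is exactly zero (the variance estimate is already on
the boundary) the p-value is 1 by construction and no simulation is
needed.

## DBH: rank-transformation sampling

Simulated trees receive diameters matching the empirical census
distribution without a parametric form: reference DBHs are mapped to
normal scores $\Phi^{-1}((r-0.5)/n)$ (midranks for ties), and sampling
inverts the map by monotone linear interpolation in (score, dbh) space
from standard-normal draws. Scores beyond the reference range extrapolate
linearly along the boundary slope, clamped at ±10% beyond the observed
range — the back-transform is not specified in the source, and the clamp
prevents absurd giant or minuscule trees at extreme normal deviates.

# Composing the landscape

Given a simulated forest (positions by thinning of the fitted intensity,
DBHs from the rank map) and the two phenology fits, a landscape over $s$
seasons draws four independent mean-zero normal vectors — $u, v$ (log
production) and $w, z$ (peak shift, days) — and computes, per tree $i$,
season $j$ and day $t$:

$$\lambda_{ij} = \exp(c_1 + c_2\,\mathrm{dbh}_i + u_i + v_j), \qquad
\lambda_{ij}(t) = \lambda_{ij}\,
\frac{1}{\sigma\sqrt{2\pi}}\exp\!\left(-\frac{(t - c_3 - w_i - z_j)^2}
{2\sigma^2}\right).$$

Days run on a daily grid of bin midpoints over a 365-day season starting
July 1 (weekly bins mimic trap visits); the Gaussian curve is not
renormalized over the season window because the truncated mass is below
1e-4 at the BCI parameters. `realize = TRUE` draws independent Poisson
counts per (tree, season, bin) with mean $\lambda_{ij}(t)\,\Delta t$. The
$\lambda$ scale is *trapped* fruits — exactly what the models were fit to;
converting to whole-tree production requires a user-supplied multiplier
for the fraction of a crown's fall sampled by traps, which the package
does not presume to know. Production and timing effects are drawn
independently (no production–peak correlation), matching the fitted
models.

# The synthetic-data generator

Because the original field datasets (plot censuses, aerial survey, 22
years of trap data) are not redistributable, every fitting stage is
exercised against synthetic data with exactly the structure the models
assume: a smooth covariate (kernel-smoothed random knots, standardized and
clipped to ±2.5 to keep log-link intensities bounded), an inhomogeneous
Poisson pattern, lognormal reference DBHs (median 550 mm, log-SD 0.45,
truncated to 150–2500 mm — canopy-statured adults of a large emergent),
Bernoulli detection, and trap records drawn from the two phenology models
with truncation of fall days to [0, 365]. Defaults are the published BCI
parameter set. A `fruits_scale` multiplier lets recovery experiments boost
counts beyond the sparse reality of ~943 trapped fruits (6 trees × 22
seasons) while the BCI-scale mode is retained for realism checks such as
overdispersion of season totals.

What passing recovery tests on these data do show: the estimators
implemented here recover the generating parameters of their own model
family at realistic parameter values and design sizes. What they do not
show: robustness to the ways real trap data depart from the model — trap
placement under a subset of crowns, observer effects, masting-style
season-to-season dependence, or spatial correlation between production and
location. Those are properties of the field system, not of the estimator.

# Problem sizes and numerical choices

The shipped experiments use design sizes chosen to make Monte Carlo noise
small relative to the tolerances being checked while keeping a full run on
one CPU comfortable: model II recovery at 150 trees × 30 seasons × ~30
fruits per cell; model I at 150 trees × 30 seasons with DBH uniform on
500–1500 mm; detection calibration on 10⁵ stems; spatial recovery over 50
replicate censuses of ~1500–2000 trees; envelope self-consistency over 50
replicates of 39 simulations; bootstrap type-I error over 200 outer
replicates of 199 bootstraps on a 10 × 10 design.

Other numerical decisions, collected:

* Grids: covariate and intensity surfaces default to 50 m cells; the
  covariate is evaluated at data points by bilinear interpolation, with
  points on cell boundaries resolving to the lower-left cell.
* Edge correction: kernel mass renormalized inside the window per source
  point by default; an uncorrected mode exists because only relative
  intensity matters for the inhomogeneous fit.
* Thinning simulation refuses dominating rates above 5 × 10⁶ expected
  candidates rather than silently allocating unbounded memory.
* GLMM convergence follows lme4's defaults (gradient tolerance 2e-3,
  warning not error); the detection GLM flags complete separation
  explicitly and suggests a penalized fit.
* Model II with one fruit per tree-season cell warns that the residual SD
  absorbs any tree-by-season interaction; a single cell, a single tree or
  a single season is an error, not a silent answer.
* Windows are arbitrary simple polygons in projected metres (WKT or
  GeoJSON); the season clock indexes seasons by the July 1 that opens
  them; records with missing positions contribute to DBH modelling only.

# Known limitations

* The bandwidth criterion and envelope residual type are defensible
  surrogates for choices the source analysis does not state; optima and
  envelopes need not coincide with the originals numerically.
* The Laplace approximation shows the usual mild downward bias in Poisson
  GLMM variance components at moderate designs; recovery stays within the
  documented tolerances but adaptive quadrature would sharpen it.
* No interaction or cluster point processes: observed clustering is
  modelled only through the covariate, as in the source analysis.
* Whole-tree (as opposed to trapped) fruit production is out of reach of
  the data the models are fit to and is left to an explicit user-supplied
  scaling.
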