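---
title: "Methods: multi-order elk resource selection under forage and predation risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-order elk resource selection under forage and predation risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Recovering wolf and mountain lion populations impose predation risk on elk
beyond direct killing: if elk avoid risky places, they may forfeit access to
high-quality summer forage, and that nutritional cost can propagate into
fall body fat and pregnancy — a nonconsumptive effect (NCE) of predators.
`elkrsf` implements the full analysis chain needed to ask this question
with GPS telemetry and three covariate rasters (digestible energy in
kcal/g; mountain lion and wolf relative-use surfaces):

1. fixed-kernel utilization distributions and 99% isopleth summer home
   ranges;
2. second-order (home range within population range) and third-order
   (locations within home range) used–available designs;
3. a weighted hierarchical Bayesian resource selection function (RSF) with
   per-individual random slopes;
4. fivefold by-individual cross-validation with ordinal habitat ranks;
5. a per-individual forage-versus-risk trade-off statistic;
6. Bayesian body-fat and pregnancy models with lactation interactions.

A synthetic-data generator reproduces the statistical structure the
analysis assumes, so every stage is verifiable without field data.

## The selection model

Relative use by individual $i$ at location $j$ follows the exponential RSF

$$
\omega(x_{ij}) = \exp\!\big(\gamma_{0i} + \gamma_{DE,i}\,DE_j +
\gamma_{ML,i}\,ML_j + \gamma_{WF,i}\,WF_j +
\gamma_{DE\!\times\!ML,i}\,DE_j ML_j +
\gamma_{DE\!\times\!WF,i}\,DE_j WF_j\big)
$$

where $DE_j$ is digestible energy and $ML_j$, $WF_j$ are the natural logs
of the predator relative-use surfaces (floored at each raster's smallest
positive value so zero cells do not produce $-\infty$). All continuous
covariates are centred and scaled by one sample standard deviation over the
pooled used and available rows of each order's table; interactions are
products of the standardized main effects.

The used–available contrast is estimated as a weighted Bernoulli-logit
likelihood: used rows carry weight 1, available rows weight 1000, each
row's log-likelihood multiplied by its weight. With a large available
weight the logistic fit converges to the inhomogeneous point-process
likelihood that the exponential RSF corresponds to, which is why the same
engine serves both orders of selection.

Individual coefficients are hierarchically centred,

$$
\gamma_{c,i} \sim \mathrm{Normal}(\beta_c, \sigma_c), \qquad
\sigma_c \sim \mathrm{Uniform}(0, 2), \qquad
\beta_c \sim \mathrm{Normal}(0, 2),
$$

with prior scales read as standard deviations. Random intercepts get
$\gamma_{0i} \sim \mathrm{Normal}(\beta_0, 100)$ with the scale *fixed*,
not estimated: intercepts absorb each animal's sampling intensity and
exposure, and shrinking them toward the population mean would distort the
slopes. Interactions receive their own random-effect scales under the same
Uniform(0, 2) prior. Posterior summaries are the mean and the equal-tailed
90% credible interval.

## Estimation: MAP/Laplace and Metropolis-within-Gibbs

Two modes are provided.

**`method = "map"`** (the fast default) finds the joint posterior mode by
block coordinate ascent: a penalized Newton step per individual
(coefficients given $\beta, \sigma$), then closed-form updates for $\beta$
(Gaussian conjugacy) and $\sigma$. The $\sigma$ update is a **Laplace-EM**
(marginal-mode) step: it adds each individual's conditional coefficient
variance to the squared deviations,
$\sigma_c^2 = \tfrac1n \sum_i \big[(\gamma_{c,i} - \beta_c)^2 +
\mathrm{Var}(\gamma_{c,i} \mid \cdot)\big]$.
This matters: the plain joint-mode update collapses $\sigma$ to zero
whenever individuals are weakly informed, because shrunk coefficients
understate the true spread — a well-known degeneracy of joint MAP in
hierarchical models. Intervals come from a Laplace (Gaussian) approximation
whose covariance uses the exact block structure of the joint Hessian
(individual blocks coupled to $\beta$ only through the prior), so the
Schur complement for $\mathrm{Cov}(\beta)$ is cheap.

**`method = "mcmc"`** samples the full posterior by
Metropolis-within-Gibbs: a random-walk Metropolis update of each
individual's six-coefficient block with proposal covariance calibrated
from that individual's Laplace block, an exact Gaussian Gibbs draw for
$\beta$, and an exact truncated inverse-gamma Gibbs draw for each
$\sigma_c$ (inverse-CDF sampling respects the Uniform(0, 2) upper bound).
Split-$\widehat R$ and an initial-positive-sequence effective sample size
are stored for every parameter; $\widehat R > 1.05$ or block acceptance
below 5% raises a warning rather than failing silently. Hierarchical
scale–coefficient coupling mixes slowly, so short chains will legitimately
warn; the defaults are 4 chains of 1000 warmup + 1000 kept draws.

With weights all 1, no random effects and flat priors, the MAP mode reduces
to ordinary logistic regression, which provides an external oracle: the
test suite checks agreement with `glm()` to well under $10^{-3}$ per
coefficient.

## Design tables, filters and constants

The package's defaults are the analysis constants used throughout:

| setting | default | meaning |
|---|---|---|
| season | Jul 1 – Aug 31 (inclusive) | summer, clear of calving and archery-season movements |
| rest window | 11:00 ≤ t < 18:00, dropped | midday resting fixes excluded from third-order "used"; half-open so a fix at exactly 18:00 is kept and nothing is double-counted |
| daily subsample | earliest fix per animal-day | home-range estimation only; deterministic tie rule |
| isopleth | 99% fixed kernel | summer range definition, individuals and population |
| bandwidth | per-axis reference rule $h = \hat\sigma n^{-1/6}$ | the conventional ad hoc default; configurable |
| UD grid | 250 m | isopleth resolution; finer grids are used in tests of mass accuracy |
| second order | 500 used / 1000 available per individual | polygon samples, no timestamps |
| third order | 10 available : 1 used | uniform within the individual's range |
| available weight | 1000 | point-process approximation |
| CV | 5 folds by individual, 5 bins | fold sizes differ by at most one |

Standardization is computed once per order's pooled table (one coefficient
scale per model) and recorded; second- and third-order tables are
standardized separately. Each animal-year is treated as one individual
unit, since home ranges and exposure are year-specific. Home ranges use
all daily-subsampled fixes (the midday censoring applies only to the
third-order used sample). Isopleths are clipped to the covariate raster
extent before availability sampling (Sutherland–Hodgman against the
rectangle), because the kernel smooths density past the mapped landscape.

Numerical details: the isopleth threshold is the largest density whose
superlevel set reaches the requested mass on the grid (contoured a hair
below the threshold so boundary cells stay inside); `level = 1` returns
the support. Points exactly on a cell boundary resolve to the lower-index
cell. Nearest-cell covariate lookup is the default, with bilinear behind a
flag. A constant covariate column is an error; any pairwise correlation
above 0.50 triggers a warning, and the forage–predator squared correlation
is exposed as a diagnostic because it bounds how much trade-off there is
to detect.

## Cross-validation

Each fold withholds one fifth of the individuals. The model is refit on
the rest, withheld rows are predicted at the population level, and the
20/40/60/80th percentiles of the withheld *available* predictions cut five
ordinal habitat ranks. The frequency of withheld *used* locations per rank
is tested against ranks 1..5 with a Spearman correlation; bin counts are
raw frequencies by default (an area-adjusted variant sits behind
`area_adjusted = TRUE`). Ties get midranks; for $n \le 8$ the two-sided
p-value is computed by exhaustive permutation (for a perfect ranking of
five bins that exact p is $2/120 \approx 0.0167$), otherwise by the
t approximation. Fold refits use the fast MAP mode.

## The trade-off statistic and NCE models

For each individual, high-quality forage is fixed at the 95th percentile
of standardized digestible energy across the pooled third-order table, and
the trade-off is the difference in relative use between high (95th) and
low (5th) percentiles of one predator's standardized risk covariate, the
other predator held at 0 (its standardized mean):

$$
\Delta_i = \omega_i(DE{=}q_{.95}, R{=}q_{.95}) -
\omega_i(DE{=}q_{.95}, R{=}q_{.05}).
$$

Negative values mean use of good forage is lower where risk is high — a
risk-averse trade-off. The intercept is excluded by default: the metric is
a difference of *relative* use with no absolute anchor, and
$\exp(\gamma_{0i})$ would only rescale both terms (an
`include_intercept = TRUE` flag restores it; the unnormalized exponential
form is used throughout). Coefficients are posterior means on the
standardized scale.

The trade-offs then enter small Bayesian regressions for demography:
a Gaussian model for % ingesta-free body fat and a Bernoulli-logit model
for pregnancy, each with lactation status and its interaction
(`ifbf ~ tradeoff * lact`), coefficient priors Normal(0, 100) for body fat
and Normal(0, 2) for pregnancy (scales as standard deviations), and a flat
prior on the Gaussian error scale. Age is deliberately not a covariate.
The body-fat model uses exact conjugate Gibbs sampling; the pregnancy
model uses MAP with a Laplace approximation (or random-walk Metropolis),
with complete separation detected by an unpenalized probe fit and reported
while the priors keep the estimate finite.

## What the synthetic generator emulates

`generate_landscapes()` builds smooth Gaussian random fields by separable
kernel convolution of white noise (seed-stable, no geostatistics
dependency). Digestible energy is rescaled to 0.5–3.0 kcal/g. Each
predator surface is $\exp(m z_{DE} + \sqrt{1 - m^2}\, z_\perp)$ with the
independent field residualized against $z_{DE}$, so the realized
correlation between the log-predator covariate and forage equals the
mixing coefficient exactly: $m = \sqrt{.35} \approx 0.59$ reproduces the
lion–forage squared correlation of ≈ .35 and $\sqrt{.15}$ the wolf value
of ≈ .15. The smoothing length defaults to 3 cells (750 m at the default
250 m cell): summer ranges then span many forage/risk patches, which is
what near-equal second- and third-order forage–risk correlations imply
about the real landscape.

Individuals get exact draws $\gamma_{c,i} \sim N(\beta_c, \sigma_c)$
(defaults $\beta_{DE} = 0.2$, $\beta_{ML} = -0.1$, $\beta_{WF} = 0.3$,
$\beta_{DE\times ML} = -0.1$, $\beta_{DE\times WF} = 0.03$, all
$\sigma = 0.15$; random intercepts with generator scale 0.5). Telemetry is
drawn by rejection sampling proportional to $\exp(\gamma_i \cdot x)$
inside disc home ranges (radius 3 km, ≈ 28 km² — a plausible elk summer
range) placed uniformly in the landscape; timestamps sit on a regular
2-hour schedule spanning June 15 – September 15 so the season and
rest-window filters have work to do. Coefficients act on covariates
standardized by moments pooled over all individuals' range cells — the
same scale the fitting stage standardizes to — so recovered population
effects are directly comparable to the generating values.
`simulate_used_available()` is the design-level counterpart used when
home-range estimation is not under test. Demography defaults are
calibrated once (intercept 8.88, lactation effect −2.89, error SD 2.5,
48% lactating, pregnancy intercept logit(0.76)) so that median body fat is
≈ 7.5% and the pregnancy rate ≈ 0.76 at zero trade-off effects.

Problem sizes in the test suite and acceptance script — 40 individuals ×
300 used points for recovery and cross-validation, 20 replicates for
coverage, 200 replicates of n = 27 for the demography models — are the
package's chosen verification scales: large enough for the statistical
checks to bind, small enough to run routinely.

**What the generator does not emulate.** Fixes are independent draws from
the selection surface: no movement autocorrelation, no day/night behaviour
cycles, so the rest-window filter removes a random (not behaviourally
distinct) subset. Home ranges are stationary discs, placed uniformly —
second-order fits on synthetic data therefore estimate availability
artifacts, not a planted second-order signal, and only third-order truth
is recoverable. Predator layers are static; there is no predator–prey
feedback, no year effects, no measurement error in the rasters. Passing
tests show the estimation machinery is correct under the stated model;
they do not show the model captures real elk behaviour.

## Known limitations

- With hard-edged generative ranges, a 99% kernel isopleth from ~90 daily
  fixes oversmooths: availability sampled from the estimated isopleth
  includes terrain outside the true range. Population effects remain
  within 2 posterior SDs of truth end-to-end, but per-individual
  coefficients absorb idiosyncratic availability error, inflating
  random-effect scales and degrading individual-level trade-off rankings
  (true-versus-estimated trade-off correlation ≈ 0.85–0.9 at the design
  level drops to ≈ 0.3–0.5 through the full pipeline). This is a property
  of the kernel-home-range design at these sample sizes, not of the
  implementation; an optional radial `edge_taper` in the generator
  explores softer range edges.
- The Laplace intervals in MAP mode hold the random-effect scales at their
  marginal mode, so they are slightly narrow; measured 90% coverage in the
  acceptance checks is ≈ 0.88.
- The Metropolis-within-Gibbs sampler mixes slowly in the scale
  parameters; treat $\widehat R$ warnings seriously and lengthen chains
  rather than trusting short runs.
- No geographic CRS handling (one planar metre-based system is assumed),
  no step-selection designs, no Brownian-bridge or autocorrelated kernel
  estimators, no model selection: one model per order of selection.
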