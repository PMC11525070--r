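---
title: "Modelling tree growth–survival relationships with growsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tree growth–survival relationships with growsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growsurv)
```

## The scientific problem

In forest stands, trees that grow slowly often die at higher rates than
their fast-growing neighbours. The shape and strength of this
growth–survival relationship varies along environmental gradients and is
reshaped by disturbance. `growsurv` implements an analysis pipeline for
studying this variability with tagged-tree remeasurement data from a
permanent plot network: a monodominant montane *Nothofagus* (mountain
beech) forest sampled by 216 plots of 0.04 ha (20 m × 20 m) on 85
transects across a 640–1417 m elevation gradient, measured eight times
between 1974 and 2009, and struck by a magnitude-6.7 earthquake in 1994.

## The survival model

The unit of observation is one tree over one *survival interval*. The
default schedule defines five intervals grouped into three *periods*
within which coefficients are constant:

* period 1, pre-earthquake: 1983–1987, 1987–1993;
* period 2, 0–5 years post-earthquake: 1993–1999;
* period 3, 5+ years post-earthquake: 1999–2004, 2004–2009.

Tree status gives a binary sequence $a_{i,t}$ (1 alive, 0 dead). Let
$S_{i,t-1}$ be the *annual* survival probability of tree $i$ over the
interval starting at $t-1$, of length $\Delta t$ years. Death times are
interval-censored; annual survival is treated as constant within the
interval, so

$$a_{i,t} \sim \mathrm{Bern}\!\left(S_{i,t-1}^{\Delta t}\right),
\quad \text{given } a_{i,t-1} = 1 .$$

Annual survival is modelled on the logit scale, for period regime $eq$:

$$\operatorname{logit} S_{i,t-1} = \mu_{S,eq}
 + \gamma_{y,eq}\, y_{i,t-1} + \gamma_{y^2,eq}\, y_{i,t-1}^2
 + \gamma_{bas,eq}\, bas_{i,t-1}
 + \gamma_{bas\times ele,eq}\, bas_{i,t-1} ele_j
 + \gamma_{G,eq}\, G_{i,t-2} + \gamma_{G\times ele,eq}\, G_{i,t-2} ele_j
 + \gamma_{G1,eq}\, G_{i,t-3} + \gamma_{G1\times ele,eq}\, G_{i,t-3} ele_j
 + P_{S,j,t-1},$$

with the plot-level part

$$P_{S,j,t-1} = \gamma_{dist,eq}\, dist_j + \gamma_{avP,eq}\, avP_j
 + \gamma_{LI,eq}\, LI_j + \gamma_{ele,eq}\, ele_j + \epsilon_j,
\qquad \epsilon_j \sim \mathcal N(0, \sigma_S^2).$$

Here $y$ is diameter, $bas$ the neighbourhood basal area, $G$ and $G1$
previous and lagged annual growth, $avP$ soil-available phosphorus, $LI$
the landform (terrain shape) index, $ele$ elevation and $dist$ the
distance from the earthquake epicentre. One $\epsilon_j$ is shared by all
periods: the plot effect captures time-invariant site quality, and
period-specific regimes are already carried by the fixed effects.

### Covariates and standardization

Growth covariates are annual diameter change over the two measurement
windows preceding a survival interval: for 1983–1987, *previous* growth
is 1978–1983 and *lagged* growth 1974–1978. Small negative growth rates
are retained: in a slow-growing species, routine measurement error
produces them and dropping them would bias growth upward. Window rates
above 10 mm/yr or below −3 mm/yr (strictly) flag a tree for diameter
imputation instead.

Neighbourhood competition is the basal area of all living trees inside
the 15 m × 15 m square (3 × 3 subplot block, 0.0225 ha) centred on a
tree's 5 m × 5 m subplot. Stem positions are resolved only to subplot,
so the window is discretized to subplots. Survival observations are
restricted to the four central subplots (6, 7, 10, 11), whose windows
never cross the plot boundary; all plot trees contribute to the
neighbour sums.

Covariates are centred so that "zero" is a typical tree on a typical
plot: basal area at 50 m²/ha, diameter at 164 mm, soil P at
ln-scale 2.7 (14.88 µg/g), landform index at 20°, distance at
ln-scale 2.9 (18.17 km), elevation at 1000 m. Growth rates are used
uncentred (zero growth is the natural reference). Elevation is divided
by 100 m: with raw metres, elevation coefficients of the magnitude this
system exhibits (≈ 0.24 per 100 m) would imply absurd logits across a
777-m gradient. The divisor is configurable and recorded.

### Priors, sampler and protocol

The priors are weakly informative on the logit scale: independent
$\mathcal N(0, 10^2)$ on all fixed effects and half-$\mathcal N(2)$ on
$\sigma_S$; both are configurable. With ~4,500 observations the
posterior is dominated by the likelihood for all well-identified
parameters; doubling or halving the prior scales moves posterior means
by far less than one posterior sd (the weakly-identified interaction
terms are the most prior-sensitive, as expected).

Fitting uses an adaptive Metropolis-within-Gibbs sampler written in
C++: coordinate-wise random-walk proposals for fixed effects (proposal
scales initialised at 2.4 / column scale), per-plot proposals for
$\epsilon_j$, a log-scale random walk for $\sigma_S$, and three
non-standard moves that target the posterior geometry of this model:

* a *recentring* move shifting all period intercepts by $\delta$ and all
  plot effects by $-\delta$ (likelihood-invariant; breaks the
  intercept/plot-effect confounding);
* analogous *shift* moves for each plot-constant covariate (soil P,
  landform, elevation, distance), likelihood-invariant because those
  covariates are constant within plots;
* a joint *rescaling* $\epsilon' = c\,\epsilon$, $\sigma' = c\,\sigma$
  that crosses the funnel between the random effects and their sd.

Adaptation runs during burn-in only and is frozen afterwards, so the
retained chain is a valid Markov chain with the posterior as its
invariant distribution. All randomness flows through R's RNG: a fixed
seed reproduces a fit bit-for-bit.

The default protocol is 3 chains × 50,000 iterations, burn-in 10,000,
thinning 40 (3,000 retained draws), which takes about two minutes for
the full study-scale design and brings split-$\hat R$ below 1.05 for
all parameters. A random-walk sampler needs more iterations than a
gradient sampler for the same effective sample size; this protocol is
the point where the diagnostics stabilise for the study-scale design.
The archival-scale protocol suited to the full field dataset (3 chains,
150,000 post-burn-in iterations, burn-in 10,000, thinning 3) is
available through `mcmc_config()`. Convergence is reported per
parameter (split-$\hat R$ and an initial-positive-sequence effective
sample size); any $\hat R > 1.05$ attaches a warning to the fit rather
than failing silently.

### Model comparison

Nine candidate models combine the two growth covariates and their
elevation interactions (an interaction is only allowed with its main
effect); the *base* model has no growth covariates, the *full* model has
all four blocks, and the *selected* model — the default for inference —
drops only the lagged-growth × elevation interaction. Models are ranked
by WAIC computed from the stored pointwise log-likelihoods, with the
variance-form penalty $p_{\mathrm{WAIC}} = \sum_i \mathrm{var}_s\,
\log p(y_i \mid \theta_s)$; the pointwise unit is the tree × interval
observation. The deviance $-2\log p(\mathrm{data}\mid\theta)$ is
evaluated per retained draw. Exact WAIC ties (which essentially never
occur with stochastic estimates) resolve toward the model with fewer
growth blocks.

## The synthetic forest generator

Because the field data are archived under restricted access, the
package ships a simulator that reproduces the *statistical structure*
the analysis assumes, so that every stage — including full parameter
recovery — is testable. The defaults mirror the study design: 216 plots
of 0.04 ha on 85 transects (1–8 plots each), 16 subplots per plot,
trees tagged at ≥ 30 mm, eight measurements 1974–2009, elevations
spanning 640–1417 m.

Growth is log-linear in standardized elevation, neighbourhood basal
area and diameter with Gaussian noise — about 1.1 mm/yr for a typical
tree, ≈ 2.5 mm/yr at the valley floor and ≈ 0.4 mm/yr near treeline,
declining with local competition. Each tree additionally carries a
persistent lognormal vigour multiplier (sd 0.4 on the log scale):
trees differ durably in growth through microsite and suppression
history, which is what makes the growth distribution wide (central
95 % roughly −0.1 to 4.5 mm/yr) and consecutive growth windows
autocorrelated — without it, previous and lagged growth would carry far
less survival information than remeasurement data actually do. Survival outcomes are drawn from
exactly the interval-survival likelihood the fitting module implements,
with the reference coefficient set (`default_truth()`) as truth: high
baseline survival (logit ≈ 3.7–3.9), positive growth effects weakest
0–5 years post-earthquake and strongest 5+ years post-earthquake, a
positive distance-from-epicentre effect confined to period 2, and
$\sigma_S = 0.966$. Stochastic elements are $\epsilon_j \sim \mathcal
N(0, \sigma_S^2)$ once per plot and one Bernoulli draw per tree per
interval.

The earthquake enters the simulation in two ways, deliberately kept
apart:

* *Mortality.* The period-2 coefficient regime itself generates
  distance-dependent excess mortality (a tree 6 km from the epicentre
  loses roughly a quarter of its cohort over 1993–1999 at the default
  truth, against ≈ 10 % at the reference distance). Because this runs
  through the model's own likelihood, simulated data remain exactly
  fittable. A separate `eq_extra_mortality` knob can add non-model
  mortality; it defaults to 0, since switching it on would deliberately
  break the likelihood match that parameter-recovery testing relies on.
* *Injury.* A distance-dependent fraction of survivors (≈ 25 % near the
  epicentre, ≈ 10 % at the reference distance) is marked injured in
  1993 and grows more slowly thereafter (factor 0.6). This reshapes the
  post-earthquake growth distribution — more slow and negative growers,
  as injured trees show — without touching the survival likelihood,
  since growth is a covariate.

Initial stocking varies between plots (lognormal, sd 0.45 on the log
scale, ≈ 500 stems/ha ≥ 30 mm on average) on top of Poisson noise, and
initial diameters are gamma-distributed around ≈ 165 mm. Two
considerations fixed these free parameters (no stocking tables are
available for the study): the expected number of central-subplot
tree-interval observations under the default design, about 4,500,
matches the field study's analysis sample size; and between-plot
density variation must be dominated by exogenous differences in
stocking, as in real networks, not by the accumulated imprint of the
plot survival effects. The latter matters statistically: neighbourhood
basal area responds to past mortality, so with identical initial plots
the competition covariate would correlate with $\epsilon_j$ through
mortality feedback, violating the random-effect exogeneity every GLMM
assumes and biasing the recovered competition coefficients — a caveat
that applies to the field analysis itself and is worth keeping in mind
when interpreting $\gamma_{bas}$. For the same reason, mortality in the
two pre-study intervals (1974–1978, 1978–1983, which only supply growth
windows and are never fitted) is simulated without the plot effect, so
the stand state entering the first survival interval is exogenous to
the $\epsilon_j$ the model estimates; from 1983 onwards every outcome
is a draw from the model's own likelihood.

What the generator does *not* emulate: spatial landslide geometry (no
tree coordinates below subplot resolution), the 1973 snowfall/pathogen
episode, species mixtures, masting-driven recruitment pulses, and
spatial autocorrelation between neighbouring plots beyond shared
transect elevation. Passing recovery tests on synthetic data therefore
demonstrates the estimator is correct for the assumed structure, not
that the structure exhausts real forest data.

## Data cleaning rules

* Growth outliers (> 10 or < −3 mm/yr, strict) and interior missing
  diameters are imputed from the median growth of same-plot trees in the
  same diameter tercile over the same window, anchored at the nearest
  reliable measurement (ties prefer the earlier year). When fewer than
  two tercile mates have the window, the whole plot's median is used; a
  tree with no reliable anchor is excluded with a logged reason.
* When an outlier window implicates two measurements, the
  chronologically later diameter is treated as the offender. A gross
  error at a tree's *first* measurement can therefore cascade into a
  second imputation; with outlier rates around 0.2 % this is acceptable,
  and every imputation is logged and flagged.
* Death is absorbing: dead-then-alive sequences are validation errors.
  A tree alive at an interval start but unrecorded at the end is
  excluded from that interval (not treated as dead) and logged.

## Numerical choices

* The pointwise log-likelihood uses the stable forms
  $\Delta t \log S = -\Delta t\,\mathrm{log1p}(e^{-\eta})$ and
  $\log(1 - S^{\Delta t}) = \log(-\mathrm{expm1}(\Delta t \log S))$.
* WAIC's log-pointwise-predictive-density is computed by log-sum-exp.
* Posterior percentiles are empirical type-7 quantiles.
* CSV round-trips write doubles with 17 significant digits.

## Problem sizes used in the tests

The shipped test-suite simulations are sized to run on a laptop: the
study-scale recovery check uses the full 216-plot design (~4,000
observations) with the default protocol; model-comparison direction
checks use 60-plot datasets with shorter chains across five seeds; and
the interval-calibration check uses 20 replicates of an intercept-only
model. The methods themselves have no size limits beyond memory for the
stored draws × observations log-likelihood matrix.

## Known limitations

* The plot random effect is shared across periods; a period-specific
  $\epsilon_{j,eq}$ would need a different identifiability argument.
* No spatial correlation between plots; transect structure is sampling
  metadata only.
* The imputation model is deliberately simple (plot × tercile medians);
  it is not a growth model and should not be used to analyse growth.
* WAIC penalties depend on the pointwise unit (tree × interval here);
  comparisons across different observation units are meaningless.
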