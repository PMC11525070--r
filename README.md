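# growsurv

Growth–survival analysis for tagged-tree remeasurement data from
permanent forest plot networks.

Forest ecologists have long asked whether slow-growing trees die at
higher rates, and how that relationship shifts along environmental
gradients and after disturbance. `growsurv` implements the full analysis
pipeline for studying this question with repeatedly measured, tagged
trees — the setting of a monodominant montane *Nothofagus* (mountain
beech) forest in New Zealand's Southern Alps: 216 plots of 0.04 ha on 85
transects spanning a 640–1417 m elevation gradient, measured eight times
between 1974 and 2009 and struck by an M~w~ 6.7 earthquake in 1994.

The model at its core is a Bayesian annualized interval-survival model.
A tree alive at the start of a survival interval of length Δt survives
it with probability *S*^Δt^, where the annual survival *S* follows a
logistic regression with period-varying coefficients:

logit *S* = μ_S,eq + γ_y,eq·y + γ_y²,eq·y² + γ_bas,eq·bas +
γ_bas×ele,eq·bas·ele + γ_G,eq·G + γ_G×ele,eq·G·ele + γ_G1,eq·G1 +
γ_dist,eq·dist + γ_avP,eq·avP + γ_LI,eq·LI + γ_ele,eq·ele + ε_j

with diameter *y*, neighbourhood basal area *bas* (15 m × 15 m window),
previous and lagged annual growth *G*, *G1*, plot covariates (soil P,
landform index, elevation, epicentre distance), a Normal(0, σ_S²) plot
random effect ε_j, and coefficient regime eq ∈ {pre-earthquake, 0–5
years post-earthquake, 5+ years post-earthquake}. Candidate models
differing in their growth terms are compared by WAIC. Because the field
data are archived under restricted access, the package includes a
synthetic forest simulator that reproduces the statistical structure the
analysis assumes, so the entire pipeline — including parameter recovery
— is testable end to end.

## Worked example

```r
library(growsurv)

# simulate a plot network and build model-ready observations
ds  <- simulate_forest(sim_config(n_plots = 100, n_transects = 40), seed = 42)
obs <- prepare_observations(ds$trees, ds$plots)
nrow(obs)
#> [1] 2083

# fit the selected model (both growth mains + previous-growth x elevation);
# about a minute on one core with the default protocol
fit <- fit_mcmc(obs, model_spec("selected"), seed = 1)
summarize_posterior(fit)[1:4, c("parameter", "mean", "q2.5", "q97.5")]
#>   parameter     mean      q2.5    q97.5
#> 1      mu_1 3.464419 2.0049562 4.974454
#> 2      mu_2 3.526424 2.0404410 5.170526
#> 3      mu_3 5.532373 3.6310780 7.585077
#> 4   sigma_S 0.775498 0.3955185 1.183381
```

The intercepts are logit-scale mean annual survival at the standardized
covariate zero point (a 164 mm tree in a 50 m²/ha neighbourhood at
1000 m, 18 km from the epicentre): `plogis(3.46)` ≈ 0.97, i.e. roughly
97–98 % annual survival, with plot-to-plot sd ≈ 0.8 on the logit scale.
The simulation truth for this run (`ds$truth`) has mu_1 = 3.691 and
sigma_S = 0.966, both inside the credible intervals above.

```r
# growth-survival curve, period 1 at 1000 m elevation
crv <- predict_survival_curve(fit, period = 1, elevation_m = 1000)
round(crv[c(1, 25, 50), c("growth", "mean", "lower", "upper")], 4)
#>    growth   mean  lower  upper
#> 1  0.0959 0.9641 0.8898 0.9936
#> 25 1.3259 0.9852 0.9488 0.9980
#> 50 2.6072 0.9924 0.9623 0.9997
```

Survival rises with previous growth; the curve is confined to the
central 95 % of observed growth for that period and elevation class.
`select_models()` fits the nine candidate models and ranks them by WAIC;
`run_pipeline()` orchestrates simulate → prepare → fit → select → report
into an artefact directory with a manifest. A thin command-line front
end ships in `inst/cli/growsurv`.

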