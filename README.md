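# pollenFB

Dispersal models for maize cross-pollination (CP) in small-scale farming
systems where donor and recipient fields are separated by a **field border
(FB)** — a roadway or unplanted strip a few metres wide. The package is for
researchers in gene-flow / coexistence studies who need to predict the CP
rate as a function of distance, with the border width as an explicit
covariate, and to quantify the uncertainty of those predictions.

## The models

A per-cob CP grain count $Y_s$ at distance $d$ from the nearest donor is
modelled in three layers:

1. **Effective distance** $d^*$: with the FB effect, $d^* = d - FB$;
   without it, the raw distance (compound-exponential kernel) or
   $d - 0.75$ m (modified-Cauchy kernel).
2. **Kernel** $\gamma(d^*)$, the relative donor pollen density — compound
   exponential ($K_e e^{-a_1 d^*}$ near the source, rate $a_2$ beyond a
   break distance $D$) or modified Cauchy
   ($2\beta / \pi[\beta^2 + {d^*}^2]$, far-range coefficient $c_1$) — both
   attenuated by $e^{-k\sqrt{FB}}$ when the FB effect is on.
3. **Observation model**: $Y_s \sim$ Poisson($\lambda_s$) or zero-inflated
   Poisson, with $\lambda_s = K\gamma(d^*)$, $K$ the average grain number
   per cob, and distance-dependent zero inflation
   $q_s = 1/(1+\exp(b_1 - b_2 d^*))$.

The eight combinations are coded `PExpoN`, `PExpoB`, `PCauchyN`,
`PCauchyB`, `ZExpoN`, `ZExpoB`, `ZCauchyN`, `ZCauchyB` (observation model ×
kernel × FB effect). A grid's CP rate is
$100 \sum_i \mathrm{Cob}_i / (nK)$ (percent).

The package provides maximum-likelihood fitting with multi-start
optimisation (`fit_mle`), AIC/deviance/R² and predictive correlation
(`fit_metrics`, `predictive_r`), grouped threefold cross-validation
(`crossval_threefold`), adaptive random-walk Metropolis sampling with DIC
(`run_mcmc`, `dic`), posterior-predictive 95% credible bands for the CP
rate versus distance (`posterior_predictive_band`), zero-excess
diagnostics (`zero_excess`), and a seeded synthetic field-experiment
generator with presets for the 2009-1, 2009-2A/2009-2B and 2010-1 layouts
(`make_layout_preset`, `simulate_experiment`, `paper_scale_suite`).

## Worked example

```r
library(pollenFB)

suite <- paper_scale_suite(seed = 1)       # three synthetic experiments
field <- combine_datasets(suite)           # 1685 cobs on 337 grids

fit <- fit_mle(field, "ZExpoB", seed = 1)
fit
#> Dispersal model fit: ZExpoB (n = 1685 cobs, K = 400)
#>     Ke     a1     a2      k      D     b1     b2
#> 0.6713 0.6046 0.0509 0.3567 2.8389 3.2390 0.0365
#> logLik -4035.11 | AIC 8084.22 | deviance 8070.22 | R2 0.978 | converged: TRUE
```

The fitted source strength `Ke`, near/far decline rates `a1`/`a2`, border
coefficient `k` and break distance `D` recover the generating truth
(`default_truth_params()`) closely; the zero-inflation coefficients
`b1`/`b2` are identified only through the zero pattern and are noisier.

```r
cv <- crossval_threefold(field, "ZExpoB", seed = 7)
cv
#> Threefold grouped cross-validation of ZExpoB
#>   aic        5508.6 ± ...
#>   deviance   5494.6 ± ...
#>   r_squared  0.966 ± ...
#>   r          0.9665 ± ...
```

Cross-validated AIC for the with-border model (`ZExpoB`, ≈ 5509) is far
below its no-border counterpart (`ZExpoN`, ≈ 7099) on the same bordered
synthetic data, and its predictive correlation is higher (0.97 vs 0.90) —
ignoring the border systematically underestimates CP behind it.

```r
post <- run_mcmc(field, "ZExpoB", mcmc_settings(seed = 5), init = fit$estimates)
band <- posterior_predictive_band(post, seq(0.75, 30, 0.25), fb_width = 0)
plot(band, observed = grid_summary(field))
```

`band` holds the posterior-predictive mean CP rate and its 95% credible
interval at each distance for a single future cob; models with the FB
effect produce visibly narrower bands at 3–10 m.

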