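---
title: "Modelling maize cross-pollination with a field-border effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling maize cross-pollination with a field-border effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenFB)
```

## The problem

When a genetically modified (GM) maize field sits near a conventional one,
wind-borne pollen cross-pollinates recipient plants, and the resulting
adventitious presence of GM grains must stay below labelling thresholds.
In small-scale Asian farming systems, fields are typically separated not by
long isolation distances but by a *field border* (FB) — a roadway or
unplanted strip a few metres wide. pollenFB models per-cob
cross-pollination (CP) grain counts as a function of distance from the
donor field, with the FB width as an explicit covariate, so that CP-rate
predictions and their uncertainty remain honest in bordered layouts.

The observed unit is one recipient cob: its count of CP grains $Y_s$
(identified by grain colour through the xenia effect) at a location $s$
whose shortest distance to the nearest donor plant is known. A grid (in
practice one recipient row) collects $n$ cobs, and the grid's CP rate is

$$\mathrm{CP}(\%) = 100 \cdot \frac{\sum_{i=1}^{n} \mathrm{Cob}_i}{n\,K},$$

where $\mathrm{Cob}_i$ is the CP grain count on cob $i$ and $K$ the average
total grain number per cob. $K$ is a dataset-level configuration constant
(default 400 grains, a realistic figure for glutinous maize cobs); every
conversion between counts and rates in the package parameterises $K$
explicitly.

## The model

Each of the eight dispersal models composes three layers.

**Effective distance.** All kernels act on an effective distance $d^*$.
Models *with* the FB effect subtract the border width from the raw
distance, so the first recipient row behind the border sits at $d^* = 0$;
the no-FB compound-exponential models use the raw distance unchanged; the
no-FB modified-Cauchy models subtract one row spacing (0.75 m). Raw
distances (border included, as planted) are what the data store — the
subtraction is applied per model variant, so a single dataset serves all
eight models.

**Kernel.** The relative donor pollen density $\gamma(d^*)$ declines with
distance under one of two families, each with a break distance $D$
separating a near-source and a far regime, and both families multiplied by
$e^{-k\sqrt{FB}}$ when the FB effect is on:

* compound exponential: $K_e e^{-a_1 d^*}$ for $d^* \le D$ and
  $K_e e^{-a_1 D - a_2 (d^* - D)}$ beyond, continuous at $D$ by
  construction (near rate $a_1$, far rate $a_2 < a_1$ produces the fat
  tail);
* modified Cauchy: $\dfrac{2\beta}{\pi[\beta^2 + {d^*}^2]}$ for
  $d^* \le D$ and $\dfrac{2\beta}{\pi[\beta^2 + D^2 + c_1 (d^* - D)^2]}$
  beyond, where $\beta$ sets the decline rate and $c_1 < 1$ slows the far
  decline.

The kernel is *not* a normalised density over space; it is evaluated at the
nearest-source distance only, and $\gamma$ may exceed 1 for extreme
parameter values. The package warns (rather than errors) if a fitted
kernel exceeds 1 anywhere, and clips predicted CP rates to $[0, 100]$ only
when reporting.

**Observation model.** The expected CP grain count is
$\lambda_s = K\,\gamma(d^*)$. Counts are then Poisson, or zero-inflated
Poisson (ZIP) to accommodate the excess zeros typical of far-distance
sampling: a mixture of a point mass at zero and a Poisson component, with
mixing governed by the logistic
$q_s = 1/(1 + \exp(b_1 - b_2 d^*))$ on the same $d^*$ convention as the
model's kernel.

### The ZIP weight convention

With the estimated signs of $b_1$ and $b_2$ (both positive), $q_s$ is
small near the source and grows with distance. If $q_s$ were the
probability of the Poisson component, structural zeros would dominate
exactly where CP is highest — scientifically implausible. The package
therefore defaults to taking the *complement*, $w = 1 - q_s$, as the
Poisson-component weight, which makes structural zeros increasingly likely
at long range, consistent with where zero-excess is actually observed.
The literal alternative ($w = q_s$) remains available via
`model_spec(code, zip_weight = "literal")` for sensitivity analysis.

The predicted CP rate at a location is the model mean over $K$:
$100\,\gamma$ for Poisson models and $100\,w\,\gamma$ for ZIP models.

## Fitting

`fit_mle()` maximises the per-cob log-likelihood. The likelihood is
evaluated per cob (an option aggregates to grids through the summaries, but
per-cob is the default unit throughout). Positivity-constrained parameters
are optimised on the log scale with guard bounds $|\log \theta| \le 20$;
$b_1, b_2$ are unconstrained. Each fit runs a small multi-start (default 5
starts: moment-based initial values plus jittered copies, jitter SD 0.3 on
the transformed scale), each start passing through Nelder–Mead and a BFGS
polish; the best likelihood wins, ties broken by the smaller parameter
norm. The automatic initial values derive the near rate from a log-linear
regression of nonzero grid CP rates on distance, the source strength from
the first-row CP rate, and $k$ from the first-row ratio between bordered
and borderless experiments.

AIC ($-2\ell + 2p$) and deviance ($-2\ell$) follow from the likelihood.
$R^2$ is not canonically defined for these nonlinear count models; the
package uses $1 - \mathrm{SSE}/\mathrm{SST}$ between observed and predicted
*grid-level CP rates* (unclipped predictions), the simplest definition
comparable across models, and reports `NA` when the observed rates have no
variance. Predictive ability is the Pearson correlation $r$ between
observed and predicted grid CP rates on held-out data.

`crossval_threefold()` implements the grouped protocol: observations
sharing a field design and distance form a group, each group is split
evenly (seeded) across three folds, and each fold in turn validates a model
trained on the other two. Training metrics are computed on the training
folds and labelled as such; means ± SD across the three folds are reported.

## Bayesian estimation

`run_mcmc()` samples the posterior of the four ZIP models with a
componentwise adaptive random-walk Metropolis algorithm on the transformed
scale. The default prior is noninformative: flat on $\log$ of each positive
parameter and flat on $b_1, b_2$, with wide guard bounds
($|\log\theta| \le 20$, $|b| \le 100$) keeping the posterior proper in
practice; any other prior can be supplied as a log-density on the
transformed scale. Proposal scales adapt toward a 44% per-component
acceptance rate during burn-in and are frozen afterwards, so the retained
(post-burn-in, thinned) draws come from a valid Markov chain. Chains are
bitwise reproducible from the seed.

Two settings profiles ship with the package: the `"paper"` profile
(500,000 iterations, 450,000 burn-in, thinning 25 — 2,000 retained draws —
and 200,000 posterior-predictive samples) matching the original analysis,
and the default `"test"` profile (20,000 / 10,000 / 5; 20,000 predictive
draws) used by the test suite and examples, whose chains are long enough
for the well-identified posteriors encountered here.

Model comparison uses the classical DIC,
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$ and
$\bar\theta$ the posterior mean on the natural scale; a negative $p_D$
triggers a warning rather than an error.

`posterior_predictive_band()` propagates both parameter and observation
uncertainty: per distance it draws parameters from the chain, simulates a
per-cob count, converts it to a CP rate ($100\,y/K$), and reports the
empirical 2.5th/97.5th percentiles. The default band is per cob — the
wider, honest band for a single future observation; `cobs_per_grid > 1`
gives the band of a grid mean instead.

## Zero-excess diagnostics

`zero_excess()` compares, within every (experiment, distance) group, the
observed fraction of zero-CP cobs with the Poisson zero probability
$e^{-\hat\lambda}$ at the group mean $\hat\lambda$ (the Poisson MLE — the
natural plug-in). A group is flagged when the observed fraction strictly
exceeds the Poisson probability; the per-experiment zero-excess level is
the percentage of flagged distance groups, all sampled groups counting in
the denominator. The unit is the cob by default, with a grid-total option,
since the original definition is ambiguous on this point.

## The synthetic experiment suite

Because the real per-cob data are a third-party deposit, the package ships
a generator that emulates the three field experiments rather than bundling
data. `make_layout_preset()` encodes the four layouts — `2009-1` and
`2009-2A` (no border, 82 recipient rows, first row 0.75 m), `2009-2B`
(6.75 m border, first row at the border edge, 6.75 m) and `2010-1` (7.5 m
border, 91 rows, first row 7.5 m) — with 0.75 m row spacing and 0.25 m
plant spacing. `simulate_experiment()` composes the chosen truth model
forward and draws counts; `paper_scale_suite()` bundles the three
experiments under a common truth, by default the ZExpoB model at the
posterior-mean estimates from the original data
(`default_truth_params()`).

Free settings the original experiments do not pin down were fixed once at
realistic values: $K = 400$ grains per cob, 5 cobs per grid, one grid per
recipient row. The generator reproduces the statistical structure the
analysis assumes — distance decay, the border attenuation
$e^{-k\sqrt{FB}}$, distance-dependent zero inflation — but not features of
real fields it deliberately omits: wind anisotropy, flowering synchrony,
meteorology-driven emission, within-grid position. Passing tests therefore
demonstrate the correctness of the estimation machinery under the model's
own assumptions, not the adequacy of the model for any particular real
field.

## Numerical choices and limitations

* All pmf evaluation is in log space; the Poisson log-mass comes from
  log-gamma (`dpois(log = TRUE)`), never factorials; the ZIP zero mass is
  combined with a log-sum-exp.
* Optimiser tolerance is `reltol = 1e-10` on the objective; multi-start
  ties break on the smaller transformed-parameter norm.
* Effective distances of exactly zero are valid (first row at the border
  edge); only strictly negative values signal a geometry/variant mismatch.
* The default predictive band is per cob, so its width is dominated by
  Poisson observation noise; differences in band width between models with
  similar fitted means are correspondingly small, and parameter-uncertainty
  comparisons are better read off the posterior SDs (or grid-mean bands
  with many cobs).
* $b_1, b_2$ are identified only through the zero pattern, and weakly so
  when zero inflation is mild; their estimates are noticeably more variable
  than the kernel parameters (visible in their larger posterior SDs).
* Problem sizes used by the test-suite checks are the package's own
  choices: the full suite (337 grids, 1,685 cobs) for recovery and
  cross-validation checks, 20 seeded replicates for recovery medians, and
  the `"test"` MCMC profile for Bayesian checks.

## A worked example

```{r example, eval = FALSE}
suite <- paper_scale_suite(seed = 1)
field <- combine_datasets(suite)

fit <- fit_mle(field, "ZExpoB", seed = 1)
fit

cv <- crossval_threefold(field, "ZExpoB", seed = 1)
cv

post <- run_mcmc(field, "ZExpoB", mcmc_settings(seed = 1),
                 init = fit$estimates)
band <- posterior_predictive_band(post, seq(0.75, 30, 0.25), fb_width = 0)
plot(band, observed = grid_summary(field))
```
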