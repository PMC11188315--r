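---
title: "Methods: grey-wolf-optimised RBF networks for soil nutrient and yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grey-wolf-optimised RBF networks for soil nutrient and yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the model, the training procedure, the choices that were genuinely open,
and what the bundled synthetic data can and cannot show.

## The problem

Orchard fertilization decisions hinge on predicting plot-level soil
nutrient status — alkaline-hydrolyzable nitrogen, available phosphorus
and available potassium, all in mg/kg — and the crop yield they support.
The relationship between nutrient contents, fertilizer applications and
yield is nonlinear, while soil attributes live on wildly different
scales (potassium near 100–200 mg/kg, phosphorus near 5–50 mg/kg).
`gwrbf` provides a hybrid regression model for this setting, together
with the surrounding workflow: standardization, evaluation metrics,
comparison baselines, a stepwise linear yield model and a seeded
synthetic-data generator.

## The model

The regressor is a Gaussian radial basis function (RBF) network. Hidden
unit $s$ responds to the squared Euclidean distance between the input
$x$ and its centre $o_s$,

$$G_s(x) = \exp\!\left(-\frac{\lVert x - o_s\rVert^2}{2\sigma_s^2}\right),$$

and a linear output layer combines the activations,
$\hat y = \sum_s w_s G_s(x) + b$. The norm is Euclidean; activations lie
in $(0, 1]$ and predictions are finite for any finite input and
parameters.

## Training: grey wolf search plus gradient polish

The hybrid trainer (`train_gwo_rbf()`) treats *all* network parameters —
centres, widths, output weights and the output bias ("threshold") — as
one flat search vector (`encode_rbf()`; widths are carried in log-space
so every real vector decodes to a valid network). A grey wolf optimizer
(GWO, `gwo_optimize()`) minimizes the mean relative prediction error
$\frac{1}{n}\sum_i |y_i - \hat y_i| / |y_i|$ on the training split.
Restricting the search to the output layer alone would make the
metaheuristic redundant with least squares, so the full vector is
searched.

GWO moves each candidate ("wolf") toward the three best-so-far solutions
$W_a, W_b, W_c$: for leader $\ell$ it draws coefficient vectors
$M_\ell = 2\omega p_1 - \omega$ and $N_\ell = 2p_2$ componentwise
($p_1, p_2 \sim U(0,1)$), forms the encircling distance
$D_\ell = |N_\ell \odot W_\ell - W|$ and the candidate
$W_\ell - M_\ell \odot D_\ell$, and averages the three candidates. The
convergence factor $\omega$ decays linearly from 2 to 0 over the
iteration budget, shifting the pack from exploration to exploitation.
Design choices that the original formulation leaves open:

* $p_1, p_2$ are drawn per component and per leader — this explores
  better than scalar draws and matches the metaheuristic's origins.
* Leaders are the best-so-far top three over *all* evaluations, with
  ties broken by earliest evaluation. This makes the best-fitness trace
  non-increasing by construction, which the tests assert.
* Positions leaving the search box are clipped to the boundary.
* The pack is initialized uniformly over the box, with one exception
  (the warm start, below).

After the search, the best network is polished by backpropagation
(`refine_rbf()`): full-batch gradient descent on mean squared training
error with a backtracking line search. By default each polish epoch
takes the gradient step only on the nonlinear parameters (centres and
log-widths) and re-solves the linear output layer exactly by
ridge-regularized least squares — separable least squares, which is far
better conditioned than descending through the linear layer. The ridge
penalty (`1e-6` per training record) exists purely to keep output
weights bounded when activation columns become nearly collinear; the
polish also floors log-widths at the search box's lower edge so no unit
can collapse into a spike on a single record. The polish never returns a
network with a higher training loss than its input (the incumbent is
kept in the running best).

Two deliberate deviations from a "search-only" reading of the hybrid:

* **The polish is on by default.** The hybrid method's description
  includes a backpropagation optimisation step alongside the wolf
  search, and in our experience the search alone places centres well but
  leaves several points of relative error on the table; the gradient
  polish is what turns a good basin into a good fit.
* **One wolf is warm-started** at the conventional RBF recipe
  (farthest-point centres, mean nearest-centre-distance width,
  least-squares output layer — exactly the plain baseline,
  `train_plain_rbf()`). The remaining wolves stay uniform. A hybrid
  should never do worse than the classical recipe it generalizes; the
  warm start makes that property hold by construction on the training
  fitness, while leaving the pack free to find better basins. Both
  behaviours are config flags (`refine`, `warm_start`).

Search bounds are data-driven: centres range over each feature's
observed `[min, max]` widened by half the range; log-widths span
`[log 0.05, log 5]` (meaningful because inputs are standardized);
output weights span $\pm 10\,\mathrm{sd}(y)$. The bias box is the same
width but centred on $\bar y$ rather than zero: targets such as yields
(~160 kg) sit far from zero, and a zero-centred box could exclude every
network able to match the target's location.

Defaults: $K = 10$ hidden units, 30 wolves, 100 iterations, 300 polish
epochs, seed-controlled throughout; identical seeds give bit-identical
models, which the tests assert.

## Standardization

Attributes are z-scored, $\bar H_i = (H_i - R)/\alpha_h$, with $R$ the
column mean. Two conventions are offered for the divisor $\alpha_h$:
the default `"stdev"` divides by the population (divide-by-$n$) standard
deviation, which is the only reading that actually delivers the claimed
"mean 0, variance 1"; `"variance"` divides by the population variance
and is retained for literal fidelity to write-ups that describe the
divisor that way. Population rather than sample moments are fixed so
results are deterministic and documented. Parameters are estimated on
the training split only and re-applied to validation and prediction
data (`apply_standardization()`), which prevents information leakage;
the high-level `fit_soil_model()` wrapper enforces this discipline and
carries the parameters inside the saved model.

## Evaluation metrics and comparison tables

`mape()` is $\frac{100}{t}\sum_j |U_j - \hat U_j| / |U_j|$ — the
standard reading of the mean relative error, guarded against
(physically impossible) zero targets. `mae()` is the mean absolute
error in target units. `r_squared()` is $1 - SSE/SST$ with $SST$ taken
about the mean of the *actual* values — the standard coefficient of
determination; descriptions that put the predicted mean in the
denominator are treated as a notation slip. Comparison tables
(`metric_comparison()`, `compare_models()`) report, for each competitor,
the percent *reduction* of MAPE/MAE and *increase* of R² credited to
the reference model: $100(\text{ref} - \text{new})/\text{ref}$ for
reductions and $100(\text{new} - \text{ref})/\text{ref}$ for increases,
the only arithmetic consistent with published comparison sentences of
this form. Raw values are returned; presentation rounds half-up to two
decimals.

## Stepwise yield regression

`forward_stepwise()` builds $Y = e_0 + e_1 X_1 + \dots + e_z X_z$ by
forward selection with a backward look: the candidate with the smallest
partial-F p-value enters while it clears `alpha_enter` (default 0.05),
and any included variable whose p-value drifts above `alpha_remove`
(default 0.10) is dropped; selection stops when nothing can enter. The
partial F-test for one candidate is computed as the t-test on its
coefficient in the enlarged model, which is equivalent.

One multiplicity decision was genuinely open. Testing each of $m$
candidates at `alpha_enter` admits *some* noise variable with
probability $\approx 1 - (1-\alpha)^m$ — over 20% for five candidates at
0.05 — so a pure-noise response would frequently gain a predictor. The
package therefore Bonferroni-adjusts the entry p-value by the number of
candidates screened at that step (default `adjust = "bonferroni"`),
keeping the per-step false-entry rate near `alpha_enter` itself;
`adjust = "none"` reproduces the classic per-candidate behaviour of
commercial stepwise implementations. With the default, simulation shows
a pure-noise model stays intercept-only in the mid-90s per hundred
replicates, and a strong two-variable signal is recovered exactly in
the mid-90s as well.

## The synthetic generator

`generate_soil_data()` emulates plot-level samples from a durian
plantation: nutrient and application-rate columns drawn independently
from normals truncated at zero (by resampling, which keeps the mean
within ~1% at the preset configurations), and a yield produced by a
configurable response on the nutrient z-scores plus additive Gaussian
noise, truncated positive. Two calibration presets reflect the two
scales reported for the same orchard system, which are mutually
inconsistent and are deliberately both offered rather than silently
reconciled:

* `"plantation"`: survey moments — alkaline-hydrolyzable N
  21.5 ± 3.0 mg/kg, available P 47.1 ± 0.6 mg/kg, available K
  117.7 ± 20.9 mg/kg; application rates calibrated from the bundled
  example plots (the survey reports none).
* `"table1"`: all moments estimated from the ten bundled example plots
  (`orchard_samples()`), whose yields sit at 160–185 kg.

Responses: `"linear"`; `"smooth"` (default),
$170 + 12\sin z_1 + 8\cos z_2 + 5 z_1 z_3$, chosen once to mimic a
diminishing-returns nutrient response with an interaction, a base yield
inside the example plots' range, and enough relative variation (CV
around 8%) that a constant predictor cannot score well on relative
error; and `"rbf"`, a planted $K=3$ Gaussian network whose true
parameters are returned for recovery tests. The default noise level of
5 kg (~3% of the mean yield) represents plot-level yield measurement
error. A correlation-matrix hook exists for stress tests; by default
nutrients are independent, as no covariance information is available.

What the generator does *not* emulate: spatial structure (no field
grids, no kriging), measurement censoring, seasonal covariates, or any
dependence of applications on nutrient status. Passing tests on this
generator therefore show that the algorithms behave as specified on
data with the documented location/scale structure — not that the model
generalizes to any particular real orchard.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own study conditions: 5,000 records only for
split arithmetic; 500 records (7:3 split) for the three-model
benchmark over 10 seeds; 300 noiseless records for planted-model
recovery over 10 seeds; 1,000 random pairs for metric oracles at
1e-12; 100 replicates for each stepwise selection rate. A full
training run (30 wolves × 100 iterations + 300 polish epochs,
$K = 10$, $n = 350$) takes on the order of a second or two on one CPU.

Other numerical fixtures: the forward/inverse standardization round
trip is exact to 1e-9 relative; least-squares output fits use the SVD
pseudoinverse (minimum-norm in the underdetermined interpolation
regime, $K = n$); ties in leader ranking keep the earliest evaluation;
ties in stepwise entry keep the earliest candidate column; the
`variance` convention and `adjust = "none"` switches preserve literal
alternative behaviours.

## Known limitations

* The benchmark compares three implemented model families; a
  nutrient-balance comparator is supported only as an externally
  supplied metrics column (`run_benchmark(external = ...)`), since no
  formula-level description of it is available to implement.
* The BPNN baseline is a single-hidden-layer sigmoid network trained by
  plain mini-batch gradient descent with the schedule
  $\mathrm{lr}_e = \mathrm{lr}/(1 + \mathrm{decay}\cdot e)$; its
  hidden-layer size (default 10) is a package choice.
* The relative-error fitness requires strictly positive targets; soil
  contents and yields satisfy this, and the generator guarantees it.
* One model is trained per target variable; there is no multi-output
  network.
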