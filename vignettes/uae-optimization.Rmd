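---
title: "Modeling and optimizing ultrasound-assisted extraction with response surfaces, a neural surrogate, and particle swarms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and optimizing ultrasound-assisted extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaeopt)
```

## The problem

Ultrasound-assisted extraction (UAE) recovers bioactive compounds from
plant by-products by cavitation-driven disruption of the matrix in a
solvent. For green coconut shell powder extracted in methanol, three
process factors control the outcome:

| factor | symbol | range | units |
|---|---|---|---|
| sonication time | A | 10–30 | min |
| bath temperature | B | 30–40 | °C |
| solid–solvent ratio (denominator of 1:X) | C | 10–30 | g/ml |

and five responses are measured on each extract: extraction yield (%),
total phenolics (mg GAE/g), total flavonoids (mg QE/g), total tannins
(mg TAE/g), and DPPH radical-scavenging antioxidant activity (%).
`uaeopt` implements the full modeling-and-optimization workflow:
a Box-Behnken design (BBD), coded second-order response-surface models
with ANOVA diagnostics, a feed-forward neural-network surrogate, and
joint maximization of the five responses by particle swarm
optimization (PSO), plus a seeded synthetic-data generator so every
stage can be validated against known ground truth.

## Design and coding

Each factor is coded affinely onto $[-1, +1]$ about its range center,
$x_\mathrm{coded} = (x - \bar x) / \tfrac{1}{2}(x_\mathrm{high} -
x_\mathrm{low})$, and `code_point()`/`decode_point()` are exact
inverses. The three-factor BBD consists of the 12 edge midpoints of
the coded cube (all four $\pm 1$ pairs over each factor pair, third
factor at 0) plus replicated center runs. An 18-run experiment
uniquely decomposes as 12 + 6 centers, so `make_bbd()` defaults to six
center replicates; that leaves 8 residual degrees of freedom for the
10-coefficient quadratic model and 5 pure-error degrees of freedom
from the replicates. Run order is deterministic standard order unless
a shuffle seed is given — the randomization actually used in the
source experiment is unreported, and the fitted model is order
invariant anyway.

```{r}
design <- make_bbd(center_reps = 6)
nrow(design)
head(design, 4)
```

## Coded quadratic response surfaces

Each response $y$ is modeled as a full second-order polynomial in the
coded factors,

$$ y = b_0 + b_A A + b_B B + b_C C + b_{AB} AB + b_{AC} AC + b_{BC} BC
   + b_{A^2} A^2 + b_{B^2} B^2 + b_{C^2} C^2 + \varepsilon, $$

fitted by ordinary least squares (`fit_quadratic()`). The five
published surfaces for this system are bundled as ground-truth
constants (`uae_ground_truth()`), kept deliberately distinct from
user fits; all five share negative time and temperature main effects
and a positive solid-solvent-ratio effect.

`rsm_anova()` characterizes a fit the way response-surface software
reports it:

* **per-term F tests** from sequential single-degree-of-freedom sums
  of squares in the canonical term order. On the BBD the linear and
  interaction columns are mutually orthogonal, so their sequential SS
  equal their closed-form values ($8b^2$ for linear, $4b^2$ for
  interaction terms); the quadratic block is handled by the same
  sequential decomposition.
* **lack of fit vs pure error**: pure error comes exclusively from
  replicated design points — in a 12+6 BBD, the center replicates.
  With no replication the lack-of-fit fields are reported absent
  (`NULL`), never zero.
* **summary statistics**: residual SD, response mean, CV% $= 100
  \cdot \mathrm{SD}/\bar y$, $R^2$, adjusted $R^2$, and predicted
  $R^2 = 1 - \mathrm{PRESS}/SS_\mathrm{tot}$ with PRESS computed from
  leave-one-out residuals via the hat matrix. CV% is always computed
  from the current fit rather than transcribed, since rounded summary
  tables are not always self-consistent.

```{r}
d <- simulate_bbd_experiment(seed = 42)
fit <- fit_quadratic(d, "yield_pct")
round(fit$coefficients, 3)
rsm_anova(d, "yield_pct")
```

## The synthetic experiment generator

The raw 18-run response table behind the published surfaces is not
available, so `simulate_bbd_experiment()` generates statistically
equivalent experiments: responses are the bundled surface values at
each coded run plus independent Gaussian noise whose per-response SD
is the residual SD reported for each fitted model (0.33, 0.54, 0.55,
1.21, 0.31 in response order), scaled by `noise_scale`. This is the
minimal noise model consistent with a homoscedastic
lack-of-fit/pure-error ANOVA. It deliberately omits two features real
data may have: cross-response noise correlation (all five assays share
each extract) and assay-level analytical replication below the run
level. Tests that pass on these simulations therefore validate the
statistical machinery, not those aspects of real assay data.
Every dataset is reproducible from its seed, which is stored in the
`"generation"` attribute.

## The neural-network surrogate

`ann_train()` fits a single-hidden-layer feed-forward network mapping
the three factors to the five responses. The forward pass follows the
classic layout: hidden pre-activation $W_{ih} x + T_h$, hyperbolic
tangent sigmoid (`tansig`, $2/(1+e^{-2x})-1$) activation, linear
output layer $W_{ho} h + T_o$. Inputs are min-max scaled to $[-1,1]$
over the declared factor ranges and outputs over the observed response
ranges — the scaling convention matching the transfer function's
range; it is recorded in the serialized model so the assumption is
explicit.

Runs are split 70/15/15 into training/testing/validation sets by a
seeded permutation (12/3/3 of 18 runs, remainder to training).
Training minimizes the full-batch MSE. Two optimizers are provided:

* **`"lm"` (default)** — damped Gauss-Newton (Levenberg-Marquardt)
  with an analytic Jacobian, the standard trainer for small dense
  networks. An epoch is accepted only if it lowers the training MSE
  (the damping factor is raised until it does), training stops when no
  damping level yields a relative improvement above $10^{-6}$ or the
  epoch budget (default 2000) is exhausted.
* **`"gd"`** — plain full-batch gradient descent. The nominal step is
  drawn once per run from the configured learning-rate range
  (default 0.5–1) and each epoch backtracks (halving) until the loss
  does not increase. This optimizer is retained for reference; at
  these learning rates it needs the backtracking to remain stable, and
  it converges far more slowly than `"lm"` on this problem.

Both are deterministic given the config seed (bitwise-identical
parameters on repeat). `select_architecture()` reproduces the
trial-and-error architecture search: `runs` restarts (default 10) per
candidate hidden-layer size, keeping the network with the highest
validation $R^2$, ties broken by lower validation MSE, then fewer
hidden units.

```{r}
s <- ann_train(d, hidden = 4, train_config(iterations = 200, seed = 1))
s
```

The published weight and bias values of the best 3-4-5 network are
bundled (`uae_fixtures()$ann`) under a documented orientation:
`W_ih` rows are hidden neurons, `W_ho` rows are output neurons. They
drive forward-pass contract tests; they cannot reproduce the published
predicted responses end to end because the normalization used upstream
of those weights was never reported.

## Particle swarm optimization

`pso_optimize()` implements standard PSO in its maximization sense.
Velocities update as
$$ v \leftarrow w\,v + c_1 r_1 (p - x) + c_2 r_2 (g - x), \qquad
   x \leftarrow x + v, $$
with independent uniform draws $r_1, r_2$ per particle *and* per
dimension each generation (the scalar notation of the recurrence is
ambiguous on this point; the per-dimension choice is the common one).
Positions are clamped to the search box with the velocity zeroed on
any clamped dimension; positions initialize uniformly in the box and
velocities uniformly within $\pm 0.2\times$ the per-dimension range.
The run executes exactly `max_generations` generations — a fixed
generation budget is the sole stopping rule.

The default configuration mirrors the study settings: 40 particles,
$c_1 = c_2 = 0.5$, inertia weight increasing linearly from 0.4 to 0.6
over the generations (the increasing schedule is adopted literally
from the source description even though decreasing schedules are more
common; the schedule is a config field, so either is available), 2000
generations.

Two behaviors of this default deserve emphasis, both established by
the package's tests:

* For **interior optima** (e.g. separable concave quadratics, or the
  interior optimum the hybrid pipeline targets) the default converges
  precisely — the sphere test reaches the origin to $10^{-3}$ and far
  beyond.
* The small acceleration constants make the default swarm strongly
  over-damped: diversity collapses within tens of generations. On
  multimodal landscapes whose global basin is narrow — three of the
  five bundled surfaces have a second, narrow summit occupying well
  under 1% of the coded cube — the default can settle on the broad
  local summit at any swarm size. The optimizer-correctness tests
  therefore use the canonical global-search setting
  ($c_1 = c_2 = 1.49445$, $w = 0.729$) with a large swarm, under which
  all five dense-grid maxima are matched to $10^{-3}$. Users facing
  possibly multimodal objectives should prefer that configuration.

```{r}
cfg <- pso_config(rbind(rep(-5, 3), rep(5, 3)), max_generations = 150,
                  seed = 1)
pso_optimize(function(x) if (is.null(dim(x))) -sum(x^2) else -rowSums(x^2),
             cfg)
```

## The hybrid optimization pipeline

`optimize_process()` composes a scalar fitness over a model's
predictions and maximizes it with PSO over the natural-unit factor
box. The source description never defines its multi-response fitness,
so the package adopts the simplest defensible aggregation and exposes
every part of it: the objective is a weighted sum (equal weights by
default) of min-max-normalized predicted responses, with
normalization ranges taken from the model (the surrogate's training
response ranges, or surface values over the design region). Any
model that predicts the five responses can drive it — a trained
surrogate or the quadratic surfaces themselves.

Validation against measured responses at the optimum uses
`percent_error()`, defined with the experimental value in the
denominator, $100\,|e - p|/|e|$ — the unique convention that
reproduces the published validation-error row exactly after 2-decimal
rounding. Reports round the optimum to whole units only in the
printed summary; serialized reports keep full precision together with
the swarm configuration and seed, so any report re-runs
bit-identically.

```{r}
gt <- uae_ground_truth()
cfg <- pso_config(rbind(c(10, 30, 10), c(30, 40, 30)),
                  c1 = 1.49445, c2 = 1.49445, inertia = c(0.729, 0.729),
                  max_generations = 300, seed = 3)
report <- optimize_process(gt, config = cfg)
report
```

Note that the joint optimum of the five quadratic surfaces under equal
weights (low time, high ratio) is not the published hybrid optimum
(15 min, 33 °C, ratio 24): the latter came from an unpublished fitness
over an unpublished network. The published validation arithmetic is
reproduced exactly from its own printed numbers:

```{r}
fx <- uae_fixtures()
percent_error(fx$validation$experimental, fx$validation$predicted)
```

## Numerical choices and degenerate inputs

* Coding round-trips are exact to $10^{-12}$; the BBD coded basis is
  well conditioned, and refits of noiseless quadratic data recover the
  generating coefficients to $10^{-8}$.
* Architecture-selection ties break toward lower validation MSE, then
  fewer hidden units.
* A constant response column makes the output scaler degenerate and is
  an error, as is training on fewer than 10 runs or a rank-deficient
  design.
* A non-finite objective value aborts a swarm run with the offending
  position reported, rather than silently clipping.
* Degenerate point bounds short-circuit the optimizer and return the
  single feasible point.
* Test problem sizes are chosen to keep the suite fast while remaining
  informative: 50 replicates for fit-quality recovery, 200 for
  coefficient-recovery calibration, 20 seeds for pipeline-level
  checks, 101³ grids for brute-force optimization oracles, and
  reduced epoch budgets wherever the check does not depend on full
  convergence.

## Known limitations

* **The surrogate is data-hungry; an 18-run design is small.** With a
  70/15/15 split, twelve training runs must constrain 30–60 network
  parameters. Unregularized training interpolates them and can
  extrapolate erratically between and beyond design points, however
  well the optimizer minimizes training MSE. The package's end-to-end
  check — train on a simulated experiment, optimize, score the found
  optimum on the generating surfaces — shows exactly this: the found
  optimum frequently captures less than 95% of the attainable
  true-surface fitness, and the check is allowed to fail to keep that
  limitation visible. Capacity is not the issue: trained on amply
  sampled surface data the same 3-4-5 network exceeds 0.95 validation
  $R^2$ routinely. Mitigations (validation-based early stopping,
  weight decay, Bayesian regularization) are deliberately outside this
  package's scope, which models the workflow as described. When the
  experiment budget is fixed at 18 runs, the quadratic surfaces
  themselves are the more trustworthy optimization model, and
  `optimize_process()` accepts them directly.
* **The published optimum is a qualitative benchmark only.** The raw
  18-run table, the normalization behind the published network
  weights, and the exact fitness definition are all unavailable, so
  recovering the published optimum (15 min, 33 °C, ratio 24) or its
  predicted responses by retraining is not an achievable target; the
  bundled constants support exact checks of the arithmetic
  (forward pass, percent errors, surface evaluations) instead. It is
  also worth noting that the published predicted optimum responses
  exceed the observed response ranges — surrogate extrapolation beyond
  its training outputs, which the package reports as-is rather than
  correcting.
* **Simulated noise is idealized** (Gaussian, homoscedastic,
  independent across responses), as described above.
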