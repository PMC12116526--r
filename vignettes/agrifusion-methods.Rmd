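---
title: "agrifusion: models, design choices and numerical details"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{agrifusion: models, design choices and numerical details}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrifusion)
```

`agrifusion` couples three components around a synthetic multi-zone field
simulator: a Gaussian anomaly detector over fused multimodal features, a
certified concave optimizer for budgeted resource allocation, and a
closed-loop feedback controller. This vignette explains the models and
their assumptions, the parameters that matter, and the numerical and
design decisions, in the package's own terms.

## The synthetic field

A field is partitioned into `n_zones` management zones laid out row-major
(0-based) on a `rows x cols` grid. Four per-zone environmental variables
are tracked: soil moisture and nutrient index on [0, 1], temperature in
degrees Celsius, and a canopy vigor index on [0, 1] — an NDVI-like
condition summary that every stress archetype depresses, which is what
lets visually distinct stresses (fungal lesions, insect damage) share one
yield pathway.

Each variable follows an AR(1) process around its long-run mean with
autocorrelation 0.8 per step; innovations are spatially correlated across
zones through a Gaussian kernel exp(−d²/2ℓ²) on grid distance with length
scale `env_corr_length` (default 1.5 cells, so neighboring zones co-vary
but opposite field corners are nearly independent). At `t = 0` the process
starts from its stationary distribution; bounded variables are clipped
after every update. ℓ → 0 degenerates to independent zones, which the
tests verify by Monte-Carlo correlation.

**Stress archetypes.** Four injectable stresses shift target zones' means,
scaled by a severity in [0, 1]: drought (moisture −0.4, vigor −0.3,
temperature +1.5), nutrient deficiency (nutrient −0.5, vigor −0.2),
fungal infection (vigor −0.4, moisture +0.05) and insect pests (vigor
−0.35). Fungal infection and insect pests additionally overlay zero-mean
speckle (sd 0.15 and 0.10 per unit severity) on affected zones' imagery —
a lesion / chewing-damage texture signature. The magnitudes are package
constants chosen so that a severity-1 stress displaces zone features by
several times the render noise while staying inside physical ranges; the
shift direction is what matters for the contracts (yield monotonicity in
severity, detectability). Shifts of multiple events accumulate additively
and are clipped once, so events on disjoint zones commute.

**Observations.** Satellite (8×8) and UAV (16×16, deliberately finer)
grids carry three channels — vigor, moisture, nutrient — rendered by
nearest-zone upsampling plus N(0, 0.05²) render noise; ground sensors
report each zone's state plus N(0, 0.02²) sensor noise; the weather block
is a field-level AR(1) window (24 steps × 4 variables). `zone_features()`
aggregates imagery back to per-zone channel means and stacks the sensor
vector, giving d = 10 features per zone. The weather block is field-level
and is deliberately not duplicated into every zone's feature vector: a
constant column would make the fitted covariance singular.

**Yield.** The generating response is

Y_i = β₁u_w + β₂u_f + β₃u_p − γ(u_w+u_f+u_p)² + w_envᵀ(p_i − p̄) + η,

with defaults β = (0.8, 0.6, 0.4), γ = 0.01, and η ~ N(0, 0.5²). The
linear environmental modifier (weights 2, 0, 2, 3 on moisture,
temperature, nutrient, vigor deviations) vanishes at the reference state,
so the noiseless reference yield is exactly the closed-form
diminishing-returns response that the optimizer maximizes — one ground
truth shared by the generator, the optimizer and the parameter-recovery
test. Units are fixed by convention (water mm, fertilizer kg/ha,
pesticide L/ha, yield in index units); the defaults put the unconstrained
per-zone optimum at m/2γ = 32.5 input units against a per-zone water
budget share of 20 and cap of 30, so all three constraint regimes
(interior, budget-bound, cap-bound) are exercised.

**Reproducibility.** All randomness flows through one master seed;
consumers (environment, weather, rendering, yield noise, training,
controller) draw from sub-streams derived with fixed documented offsets
(`derive_seed()`), so repeated runs are bit-identical and streams do not
collide across time steps.

## Anomaly detection

The normal model is a Gaussian fitted on normal-condition feature rows:
mean μ, covariance Σ = (1−a)S + a·diag(S) with shrinkage a ∈ [0, 1]
(default 0.1 — enough to stabilize small-sample fits without visibly
biasing large-sample ones; positive-definiteness is verified by Cholesky
and a failure suggests raising a). Scores are Euclidean or Mahalanobis
(default) distances from μ. The threshold τ is the empirical q-quantile
(linear interpolation) of held-out normal scores, so fresh normal zones
are flagged at rate ≈ 1 − q; under the Gaussian model the Mahalanobis
score is a monotone transform of the negative log-likelihood, so score
thresholding and likelihood thresholding coincide — the tests assert the
rank equivalence exactly. A zone is anomalous strictly above τ; ties are
normal. Degenerate 0/0 metrics (e.g. precision with nothing flagged) are
reported as 0 and flagged in an `undefined` field rather than NA, so
downstream aggregation never propagates missingness silently.

## Fusion mathematics

The fusion blocks are deliberately small linear-algebra implementations
whose contracts can be checked exactly:

- **Encoding/projection**: per-modality linear maps (no bias) to a shared
  dimension d (default 16, key dimension d_k = 8, one attention head —
  desk scale). Spatial modalities keep their (H, W) token layout.
- **Modality weighting**: the per-modality relevance score is the mean of
  the entries of F_m W_m, and the weights are the softmax across
  modalities. A matrix-valued score with a scalar-per-modality output is
  dimensionally ambiguous; taking the mean is the minimal reading that
  produces one convex weight per modality.
- **Spatial attention**: softmax over all H·W locations of a 1×1-conv
  score, then Hadamard reweighting broadcast over channels.
- **Cross-modal attention**: C = softmax(QKᵀ/√d_k) row-wise with shared
  projections W_q, W_k (d×d_k) and W_v (d×d). The fused vector
  F_fused = Σ_m C_m V_m needs a query definition to be well-typed; one
  learned global query token attends to each modality's keys. The
  residual F_final = F_fused + Σ_m F_m adds token sets of different
  cardinalities, so each modality is mean-pooled to one d-vector first —
  the only way the sum is well-defined without extra structure. The
  stored representation keeps `f_fused`, `residual_sum` and `f_final`
  separately, and the residual identity is asserted to 1e-12 (IEEE
  doubles do not guarantee `(a+b)−a == b` bitwise).
- **Temporal aggregation**: transformer mode (default) adds sinusoidal
  positions and applies one self-attention layer, returning the last
  token; a tanh recurrent cell h_t = tanh(W_h x_t + U_h h_{t−1} + b_h) is
  kept as the reference recurrent contract. The pipeline order is encode
  → spatial attention → cross-modal fusion → temporal aggregation; the
  blocks are exposed individually so other orders can be composed.

All softmax computations subtract the row maximum before exponentiation,
so saturated logits (the one-hot attention tests use logit 50) cannot
overflow.

**Toy training.** `train_toy_detector()` trains the modality softmax
mixing scores and a logistic head jointly by full-batch gradient descent
with analytic gradients (including the softmax Jacobian), on balanced
stressed/normal zone snapshots from the simulator, split by snapshot into
training and held-out halves. The encoder projections stay at their
seeded initialization: for a toy loop on linearly separable features this
is honest gradient descent at the scale the package targets, and
backpropagating through the attention stack would add complexity without
changing any tested contract. `lr = 0` provably leaves every parameter
untouched, a NaN loss aborts with advice to lower the rate, and training
is deterministic given the seed.

## Constrained allocation

O(U) = Y(U) − λ₁C(U) − λ₂E(U) is concave (linear minus a
positive-semidefinite per-zone quadratic), so first-order stationarity on
the convex feasible set certifies global optimality. The solver is
projected-gradient ascent with Nesterov acceleration and a monotone
restart: if the extrapolated step fails to increase the objective, the
momentum is reset and a plain projected step with step size 1/L is taken,
which is guaranteed ascent (L = 6γ is the gradient's Lipschitz constant —
the per-zone Hessian is −2γ·11ᵀ with spectral norm 6γ). The objective
trace is therefore non-decreasing, which the tests assert per iteration.

The feasible set factors per resource into capped simplices
{0 ≤ u ≤ caps, Σu ≤ B}; Euclidean projection is exact: clip to the box,
and if the budget is exceeded bisect the uniform shift θ so that
Σ clip(v−θ, 0, caps) = B (200 bisection steps, resolving θ to ~1e-15
relative). Convergence is declared when the iterate movement and the KKT
fixed-point residual max|U − Proj(U + ∇O)| fall below tolerance
(defaults: tol 1e-10, max_iter 10 000); non-convergence flags the plan
with a warning rather than failing.

The closed-form unconstrained optimum (`analytic_unconstrained_optimum`)
puts the whole per-zone total m_max/2γ on the argmax net-margin resource,
with ties broken deterministically to the lowest resource index; if no
margin is positive the optimum is zero. The brute-force
`grid_search_allocation()` oracle enumerates one zone's grid exhaustively
and answers two-zone instances with a cumulative-max table over the
residual-budget box, so it stays exact and polynomial; a grid of step h
can differ from the continuum optimum by at most L_∇·h per coordinate,
and the tests use the documented allowance 3(max|m| + 2γΣB)·h.

Negative marginal yields at large totals are possible in the quadratic
model; allocations are box-capped and not otherwise safeguarded — the γ
term is itself the over-application penalty. The trade-off surface is
exposed as a (λ₁, λ₂) grid sweep (`pareto_sweep`) rather than a vector
optimizer, consistent with weighted-sum scalarization.

## Priority allocation

r_i = w_h H_i + w_y ŷ_i + w_pᵀ p_i, with the convention that higher H
means worse condition, so detector anomaly scores plug in directly as H
and stressed zones draw more resources. Negative scores are floored at
zero before the proportional split u_i = r_i/Σr·B (a zone cannot receive
a negative amount); if no score is positive the call errors, or splits
uniformly when explicitly allowed. Cap handling clips to caps and
redistributes the surplus proportionally to the original scores among
zones still below cap — the redistribution rule that preserves
proportionality among unconstrained zones — repeating until the surplus
is gone; every pass saturates at least one zone, so at most N passes run.
On exit Σu = min(B, Σcaps) to 1e-9, with any unallocatable remainder
reported as an attribute. An over-budget input vector (which arises from
the additive feedback update) is first scaled down proportionally, which
cannot violate caps.

## Feedback control

Deviations are ΔY = Y_obs − ŷ and Δp = p_obs − p_pred. The allocation
update u(t+1) = u(t) + α_r·ΔY adds yield units times a resource-per-yield
rate; the rule is kept literal and feasibility is restored afterwards by
clipping to [0, caps] and re-projecting over-budget columns, so every
logged plan is feasible. A feasible plan with ΔY = 0 is returned
bit-identically — the fixed-point contract. Priorities evolve as
r(t+1) = r(t) + βᵀΔp; the default β = (−0.5, 0, −0.5, −0.5) raises a
zone's priority when its moisture, nutrient or vigor comes in below
prediction. Default learning rates α_r = (0.10, 0.05, 0.01) are
deliberately conservative artifact defaults: with the default noiseless
scenario the loop is stable there (the tests assert the fixed point and
the monotone ramp under a biased predictor), while large rates trip the
non-finite-state abort that names α_r. Updated priorities re-enter the
proportional allocation only when `reallocate_every` is set; by default
the loop evolves allocations through the additive rule alone, keeping the
two mechanisms separable for analysis.

The default predictor is the scenario's own noiseless response (a perfect
model), which isolates controller behavior; the interface is a plain
function `(U, env) -> list(y_hat, p_pred)` so the learned pipeline or a
deliberately biased model can be plugged in.

## Interfaces

Configuration is nested YAML/JSON with strict schema validation (unknown
keys are rejected by name — a typo guard) and defaults filled in; every
artifact-producing CLI run writes a manifest with the seed and an FNV-1a
hash of the canonical config JSON, and no timestamps, so identical runs
are byte-identical. Zone tables are RFC 4180 CSV with 0-based integer
`zone_id` keys and floats at 17 significant digits (lossless double
round-trip). Observation bundles are one CSV per modality plus a JSON
manifest of array dimensions — plain text, loss-free. Time is half-open
[0, T).

## Test and verification scale

The suite verifies contracts at deliberately small sizes chosen as
adequate for the statistical claims: two-zone instances against the
exhaustive grid oracle (step 0.05), 50 random parameter draws against the
closed form, 1 000 random draws for allocation conservation, n = 2 000
held-out normal zones for calibration (binomial band ±2√(pq/n) ≈ 0.01),
20 replicates for power monotonicity at shifts 0/1/2/4σ, 500 simulated
allocation–yield pairs for parameter recovery at 5% relative noise, ≤
8-token attention inputs against the double-loop oracle at 1e-10, and a
16-zone scenario for the toy detector. `scripts/acceptance.R` recomputes
the same quantities from scratch under a caller-supplied seed.

## Known limitations

- Imagery is a smooth per-zone field plus noise: no spectral band
  physics, no real NDVI computation, no georeferencing, no point clouds.
- The yield model is the quadratic diminishing-returns form with a linear
  environmental modifier and Gaussian disturbance; it contains no crop
  phenology or process dynamics, so passing tests demonstrate correctness
  of the methods, not agronomic realism.
- The detector is a single Gaussian; multimodal normal regimes would need
  mixture or density-ratio models outside this scope.
- The fusion stack is one attention head at toy dimensions; no GPU path,
  no pretrained weights, no deep backbones.
- Stability of the feedback loop is demonstrated empirically at the
  shipped defaults, not proven control-theoretically.
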