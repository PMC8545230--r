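---
title: "Squirrel search optimizers, wrapper selection and metaheuristic-trained perceptrons: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Squirrel search methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(squirrelsearch)
```

This vignette documents the models implemented by **squirrelsearch**, the
parameters that matter, the places where the published formulation is silent
and the package had to make a choice, and what the synthetic-data tests do
and do not demonstrate about real data.

## The squirrel search model

A population of `n` candidate solutions lives in a box `[lower, upper]^d`.
After every evaluation the agents are ranked by fitness (minimization
throughout; maximize by negating the objective at the boundary):
the best agent sits on the *hickory* tree, ranks 2–4 on the three *acorn*
trees, and the rest on *normal* trees. Ties are broken by lower agent index
(stable sort), which makes runs reproducible.

Three glide moves run each iteration: acorn agents glide toward the hickory;
a uniformly random half of the normal agents glide toward a random acorn, the
other half toward the hickory. A glide is

    x  <-  x + d_g * G_c * (target - x)

with the gliding constant `G_c = 1.9` and the gliding distance
`d_g ~ Uniform(0.5, 1.11)` redrawn per move. The step factor `d_g * G_c`
spans roughly 0.95–2.11, so a glide usually lands *past* the target on the
opposite side — an aggressive exploit/overshoot balance that contracts the
population geometrically around the best agent while it keeps improving.
With probability `P_dp = 0.1` (the predator presence probability) a glide is
abandoned for a uniform random position, the algorithm's main exploration
device. Positions are clipped to the box after every update; the published
formulation does not specify boundary handling and clipping is the least
surprising rule.

Stagnation is monitored through the seasonal constant: the Euclidean
distances from the three acorn agents to the hickory. When the smallest
distance falls below the decaying threshold `1e-6 / 365^(2.5 t / t_m)` the
normal agents are relocated by a Lévy flight across the box,
`lower + Levy * (upper - lower)`, where each Lévy component is
`0.01 r_a sigma / |r_b|^(1/beta)` with `beta = 1.5` and the closed-form scale
`sigma` (`levy_sigma()`; exactly 1 at `beta = 1`). The index in the seasonal
constant is read as running over the three acorn agents (not iterations),
and the trigger fires when *any* acorn has collapsed onto the hickory —
the collective-relocation reading of the algorithm listing.

## The advanced variant (ASSOA)

ASSOA keeps the three glide cases but gates them behind a per-iteration
uniform draw `p`: when `p >= 0.5` the basic moves run unchanged (with the
gate pinned via `assoa_params(p_fixed = 1)` the two algorithms consume the
same random stream and produce bit-identical trajectories — a property the
test suite asserts). Otherwise only the normal agents move, by one of three
cases chosen by further per-iteration draws `P_a < a` and `P_d < d`:

* **diagonal**: `x + V + c1 r (x_ht - x) + c2 r (x_at - x)`, pulling toward
  the hickory and the *nearest* acorn simultaneously (the published equation
  names a single acorn without choosing one; nearest-by-Euclidean is the
  deterministic reading);
* **vertical/horizontal**: toward a random normal agent if that agent is
  fitter, else toward the hickory, each plus the velocity term;
* **exponential**: `x + |x_rand - x| exp(b tau) cos(2 pi tau)` with
  `tau = t / t_m`. The published equation uses the raw iteration index, under
  which the cosine is identically 1 and the exponential grows without bound;
  normalizing by `t_m` keeps the move bounded and oscillatory, which is what
  the accompanying movement diagram implies.

Stagnation relocation on this variant is
`x_ht + 2 r (x_ht - x_nt)(1 - ((x_ht + x_nt)/x_nt)^2)`, evaluated
component-wise; a zero component of `x_nt` is replaced by `±1e-10` so the
ratio never divides by zero (relevant on symmetric boxes where coordinates
cross zero).

**Velocities are inert.** The formulation initializes a velocity matrix and
the diagonal/vertical cases add `V`, but no update equation for `V` is ever
given. The package evaluated the natural momentum reading
`V ← x_t − x_{t−1}` and found it actively harmful: an agent that took a
random relocation jump re-injects that jump as "momentum" on the next
advanced move, and on the 10-dimensional sphere the median final fitness
degrades by roughly two orders of magnitude, inverting the intended
improvement over the basic algorithm. The package therefore keeps `V` at its
zero initialization — the literal reading of the published description — so
the velocity terms are structurally present but contribute nothing. Users
can study momentum variants by registering a custom step function.

Randomness discipline: one sequential RNG stream per run, seeded once from
the run seed, with a documented draw order (per-agent draws inside each
case, per-iteration draws for the gates). Identical configuration and seed
reproduce every trajectory bit-identically; this is asserted for all four
algorithms.

## Baselines

GWO follows the canonical formulation: three leaders, per-dimension
coefficients `A = 2 a r1 - a` and `C = 2 r2`, candidates
`X_l - A |C X_l - X|`, new position their mean, `a` decaying linearly from 2
to 0. Note that at `a > 0` the encircling term perturbs agents even when
they sit exactly on a leader; only at the end of the schedule does the
update become the plain leader mean. The GA is generational with tournament
selection (size 3), arithmetic crossover (0.9; single-point on
binary-from-continuous spaces), per-gene uniform mutation (default `1/d`)
and elitism 1. Where published comparison configurations were not
recoverable, the package defaults to 10 agents and 100 iterations for
selection experiments — common practice for wrapper-selection comparisons —
and every value is configurable.

## The binary selection wrapper

Feature selection searches the continuous box `[0,1]^D`; a position is
binarized through the sigmoid transfer function
`1/(1 + exp(-10(x - 0.5))) >= 0.5`, which thresholds exactly at
`x = 0.5` (the boundary maps to *selected*). A mask is scored by

    F = h1 * Err + (1 - h1) * |s| / D,      h1 = 0.99

where `Err` is the misclassification rate of the wrapper classifier trained
on the 60% train split and scored on the 20% validation split. The
published work never names the classifier inside the selection loop; the
package defaults to 5-nearest-neighbours — the standard wrapper choice —
implemented in-package so that ties are deterministic (nearest-neighbour
distance ties go to the lower train-row index, vote ties to the lower class
index; the usual library implementation breaks ties randomly, which would
violate the reproducibility contract). A small `nnet`-based perceptron is
available as an alternative oracle. An empty mask scores worst-case error
1.0 by default ("worst" policy), so optimizers are repelled from degenerate
selections without any hidden mutation of their positions; a "force-one"
policy that substitutes the single best feature is available.

Because the objective depends on a position only through its mask,
evaluations are memoized per mask; in typical runs the distinct-mask count
is an order of magnitude below the call count, and the cache counters are
exposed for testing. `exhaustive_best_subset()` enumerates all non-empty
masks (guarded to `D <= 20`) in lexicographic order, so fitness ties resolve
to the smallest mask; it is the ground-truth oracle the optimizer results
are compared against.

A known and deliberate limitation surfaced by this oracle: when the class
signal is strong enough that many masks reach zero validation error, the
optimum is the *minimal* zero-error mask and the landscape is a plateau in
which the only gradient is the `0.01/D`-per-feature size penalty. The
squirrel-family glide mostly copies the best agent's mask on such plateaus
and has no single-bit neighbourhood move, so it identifies the exact minimal
mask less reliably there than GA (whose `1/d` bit-flip mutation is exactly
that move) or GWO — while still never reporting a fitness below the oracle
minimum and still concentrating its selections on the informative columns.
On rugged landscapes with genuinely nonzero errors the advanced moves pay
off and ASSOA leads the basic algorithm (the paired-seed comparison in the
test suite).

## The perceptron and its training

The classifier is a single-hidden-layer perceptron: hidden pre-activation
`S_j = sum_i w_ij x_i + beta_j`, sigmoid hidden units, *linear* output
`y_k = sum_j w_jk f_j + beta_k` (no softmax — the published output equation
is linear), class decision by argmax with lower-index ties. Inputs are
min–max scaled with statistics frozen on the train split (constant features
map to 0; out-of-range values extrapolate without clipping). Weights live in
`[-1, 1]`, enforced by the search space rather than post-hoc clipping, and
are found by any registered optimizer over the flat codec
`[w_ij row-major, beta_j, w_jk row-major, beta_k]` (round-trip exact).
Hidden width defaults to `2 n_in + 1`, the classic heuristic, since no width
is published.

The optimizer's fitness is the misclassification rate on the **development
set** (train + validation rows). With gradient-free training the empirical
error is the only training signal; scoring it on the 20% validation rows
alone would leave the 60% train rows without any influence on the weights
and quantize the fitness at 1/(0.2 n). Measuring on the combined
non-test rows keeps the signal fine-grained while the 20% test split is
still touched exactly once, for the final metrics.
`make_mlp_objective(fitness_split = "validation")` restores the
held-out-only variant for users who want the selection signal disjoint from
the training rows. Multi-class problems use one output per class
(one-vs-all labels).

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their specification and seed.

* `generate_planted()` plants `k` informative columns whose class means are
  `delta` noise-standard-deviations apart, optional jittered redundant
  copies, and independent noise columns, then shuffles columns with a
  recorded permutation. Defaults (150 samples, `D = 10`, `k = 2`,
  `delta = 3`, no redundancy) give a moderately strong signal: roughly the
  regime where one or two features separate the classes on a 30-point
  validation split.
* `generate_separable()` places two balanced classes at distance at least
  `margin` on either side of a random hyperplane, and returns the hyperplane
  for constructive oracles (tests encode it as perceptron weights and verify
  zero error). Optional label noise bounds the best achievable error.
* `generate_feature_fixture()` produces non-negative, block-correlated
  columns from rectified Gaussian factors with a mild 3-class shift in 5% of
  columns — a statistical stand-in for pooled convolutional activations
  (correlated non-negative blocks), with no attempt at visual or
  distributional fidelity to any particular network.

Passing tests on these tables shows that the optimizers recover planted
structure, that selection concentrates on informative columns, and that the
full pipeline is deterministic and internally consistent. It does not show
that selected subsets of real CNN features transfer clinically, nor
reproduce any published accuracy on image datasets: those depend on external
data outside this package's scope.

## Statistics

`wilcoxon_rank_sum()` uses midranks throughout. For pooled sizes up to 20 it
is exact: via the null Wilcoxon distribution when tie-free, otherwise by
full enumeration of all `choose(m+n, m)` midrank assignments (the library
routine cannot produce exact p-values under ties). Larger samples use the
normal approximation with tie-corrected variance and continuity correction.
Two-sided p doubles the smaller tail, capped at 1 — so identical samples
give p = 1 and the textbook `{1,2}` vs `{3,4}` case gives 1/3. Simulated
type-I error at the 5% level with `m = n = 10` sits near 4% (the exact test
is conservative at discrete sample sizes); the calibration is recomputed by
the acceptance script. One-way ANOVA is fitted through `lm`, and the
two-group F agrees with the pooled t² identity to floating-point accuracy.
AUC is the normalized Mann–Whitney statistic from the same midrank
machinery, cross-checked against an independent ROC implementation in the
tests. No multiple-testing correction is applied in the comparison report;
the pairwise tests are reported as-is.

`compare_algorithms()` pairs runs by seed: run `j` of every algorithm sees
the same dataset realization and run seed, so between-algorithm contrasts
are within-realization. Summary tables report mean error, mean relative
subset size and mean/best/worst/sd fitness over runs (sd with the `M - 1`
denominator).

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under a minute on one CPU: sphere convergence
at `d = 10`, 30 agents, 200 iterations over 10 seeds; selection-oracle
comparisons on five planted tables at `D = 10` with 20 agents and 50
iterations; feature-recovery at `D = 30`; perceptron training at
`d = 10` (275 weights), 30 agents, 100 iterations; 2,000 null pairs for the
type-I calibration. Floating-point comparisons against closed forms use
relative tolerances of `1e-12`–`1e-15`; oracle-match comparisons use
`1e-12` absolute on fitness values, far below the `0.001` fitness
granularity of one feature at `D = 10`.
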