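---
title: "Aspiration dynamics of multiplayer games: model, oracle and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aspiration dynamics of multiplayer games: model, oracle and protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspidyn)
```

## The model

A population of `N` individuals each holds one of two strategies, A or B.
Payoffs come from a symmetric d-player game: an A-player facing `k`
A-coplayers earns `a_k`, a B-player earns `b_k`, `k = 0, ..., d-1`
(`payoff_table()`). Individuals sit either in a well-mixed population
(coplayers drawn uniformly from everyone else, afresh at each interaction)
or on a simple undirected network, where coplayers are drawn from the
focal's neighbourhood; every node therefore needs at least `d - 1`
neighbours. On a *regular* network of degree exactly `d - 1`, the focal
always plays with its full neighbourhood.

Updating is self-referential rather than imitative. At each elementary time
step one individual `i` is picked uniformly at random, plays one game (or,
under the averaged scheme, the `d` games organised by itself and each of its
neighbours), and then switches its strategy with probability

$$p_i = g_i\!\left(\beta\,(e_i - \pi_i)\right),$$

where `e_i` is its personal aspiration, `\pi_i` its realised payoff, `\beta
\ge 0` the selection intensity, and `g_i` a decision function that is
differentiable, strictly increasing and strictly inside (0, 1)
(`decision_function()`, axiom checks in `validate_decision_function()`).
The canonical choice is the Fermi function `g(x) = 1/(1+e^{-x})`. Because
`0 < g < 1` everywhere, no state is absorbing: the chain on the `2^N`
strategy profiles is ergodic and has a unique stationary distribution
`\kappa`. The quantity of interest is the stationary abundance of A,
`E_\kappa[\sum_i s_i / N]`, and in particular whether it exceeds one half.

Aspirations are personal traits. They may be assigned from a file
(`load_aspirations()`) or sampled (`sample_aspirations()`) from the
distributions used throughout the simulation studies: homogeneous (default
level 2), uniform on `[0, 1]` or `[0, 5]`, the bimodal mixture
`0.4\,N(2.5, 0.5^2) + 0.6\,N(4.5, 0.5^2)` (component indicator then an
untruncated normal draw), and the power law with density `f(x) = 2x^{-3}`
on `x \ge 1`, sampled by inversion of `F(x) = 1 - x^{-2}` so the smallest
possible value is exactly 1. Aspirations are deliberately not clipped: they
may be negative or exceed every payoff, which is what makes the
strong-selection regime interesting (see *Limitations*).

## Two neutrality results and the σ-rule

Two exact facts anchor everything:

1. **Vanishing selection.** At `\beta = 0` every individual switches
   blindly with probability `g_i(0) > 0`, independently of payoffs; each
   `s_i` is then a symmetric two-state chain and the stationary abundance
   is exactly 1/2 — for *any* aspirations and any admissible decision
   functions, including heterogeneous ones.
2. **Neutral mutants.** If all payoff entries equal a constant `h`, the
   flip probability of individual `i` is `g_i(\beta(e_i - h))` in every
   state — again payoff-independent and symmetric between the strategies —
   so the abundance is exactly 1/2 at *every* selection intensity.

Strategy A is therefore favoured under weak selection precisely when the
first derivative of the abundance with respect to `\beta` at 0 is positive.
That derivative is exactly linear in the payoff entries (each transition
probability differentiates to `g_i'(0)(e_i - \pi_i)`, and `\pi_i` is linear
in the entries), and — the central, counterintuitive result — the
aspiration terms cancel identically. On a regular network of degree
`d - 1` the criterion collapses to

$$\sum_{k=0}^{d-1} \sigma_k\,(a_k - b_{d-1-k}) > 0,
  \qquad \sigma_k = \binom{d-1}{k},$$

the same binomial structure coefficients as in the well-mixed population
(`sigma_theoretical()`, `criterion_lhs()`). The coefficients are
nonnegative, palindromic, and independent of both the payoff entries and
every aspiration level. `critical_entry()` solves the criterion boundary
for one entry; for the three-player family `a = (a_0, 2, 1)`,
`b = (4, 1, 1)` it gives the threshold `a_0 = 2`.

The package treats ties (`|criterion| \le 10^{-12}`) as "neutral" rather
than as favouring either strategy: the criterion is a strict inequality and
the first-order term carries no information on the boundary.

### How weak is weak?

The criterion is a first-order statement in `\beta`. Comparing the switch
probabilities from A and from B, the quadratic term is negligible when

$$\beta \ll \frac{g'(0)}{|g''(0)|\,\left[\max_i |e_i| +
  \max_k\{|a_k|, |b_k|\}\right]},$$

implemented in `weak_selection_bound()`. The bound shrinks as the largest
aspiration grows — populations with aspirations on `[0, 5]` need weaker
selection than ones on `[0, 1]`. For the Fermi function `g''(0) = 0`, the
quadratic term vanishes identically and the bound is reported as infinite;
the returned value is a scale, not a sharp threshold.

## The exact oracle

`build_chain()` enumerates all `2^N` states (capped at `N = 14`, i.e.
16,384 states) and assembles the sparse single-flip transition matrix
`P[s, s^{(i)}] = g_i(\beta(e_i - \pi_i(s)))/N` with a lazy diagonal. On
regular structures the payoff is deterministic given the state; in
well-mixed mode, and on any network where a focal has more than `d - 1`
neighbours, the uniform coplayer draw is marginalised *inside* the flip
probability with hypergeometric weights — exact, because coplayers are
resampled afresh at every step. The stationary vector is obtained by a
sparse LU solve of `\kappa^T(P - I) = 0` with the normalisation replacing
the last (redundant) equation, plus one step of iterative refinement; a
dense eigenvector route (`aspidyn:::stationary_eigen`) confirms it in the
tests to `10^{-10}`.

The oracle turns the theory into measurements:

* `exact_abundance()` reproduces both neutrality results to `10^{-10}`.
* `abundance_derivative()` differentiates the abundance at `\beta = 0` by
  central differences with `h = 10^{-4}`. Because the abundance is smooth
  and the solver residual is near machine precision, the `O(h^2)`
  finite-difference error is ~`10^{-8}`, far below the `10^{-6}` tolerance
  used in the aspiration-independence tests.
* `derive_sigma_numeric()` exploits the linearity of the criterion: set
  `a_k = 1`, every other entry 0, and differentiate. After dividing by the
  `k = 0` value the binomial pattern `(1, 2, 1)` emerges for `d = 3` — on
  rings, on the complete/well-mixed population, and (a point the theory
  only conjectures) under the averaged payoff scheme as well.

A useful exact by-product, used to size every stochastic experiment below:
for the Fermi rule on a ring the abundance deviation under weak selection is

$$\bar{x} - \tfrac12 \;\approx\; \beta \cdot \frac{g'(0)}{2^{d}} \cdot
  \sum_k \sigma_k (a_k - b_{d-1-k}),$$

numerically `\partial \bar x/\partial\beta = 1/32` for the reference game
`a = (3,2,1)`, `b = (4,1,1)` (criterion value 1), independent of `N` from
6 to 12 and of the aspiration profile.

### Numerical choices and degenerate inputs

* Central differences with `h = 10^{-4}`: large enough that solver noise
  (`\sim 10^{-13}`) is negligible after division by `2h`, small enough that
  curvature bias stays below `10^{-8}`.
* The stationary solve assumes the chain is *numerically* ergodic. If
  `\beta(e_i - \pi_i)` is so negative that a flip probability underflows
  (below `10^{-12}`), the chain is numerically reducible — its true mixing
  time exceeds `10^{12}` steps, so the stationary distribution is
  physically unreachable too — and `build_chain()` warns rather than
  returning a silently arbitrary kernel vector.
* `derive_sigma_numeric()` refuses to normalise when the `k = 0`
  derivative vanishes (it never does on the structures treated here, where
  `\sigma_0 = 1 > 0`).
* Equal-entry (neutral-mutant) designs are excluded from the regression
  design for the same reason: they carry no first-order signal.

## The Monte-Carlo engine

`run_chain()` iterates the elementary update from an independent
Bernoulli(`init_fraction_A`) initial state and averages the abundance over
the post-burn-in steps. When every individual uses the Fermi function the
loop runs in compiled code (~10^7 updates/s on one core) driven by R's own
RNG, so `set.seed()` governs reproducibility end to end; arbitrary —
including per-individual — decision functions fall back to a pure-R
reference loop that the tests validate against the oracle on small rings.

One "generation"/"time step" is one elementary focal update throughout;
the stationary averages only make sense per elementary update, and burn-in
and sample counts are expressed in the same unit.

The standard error uses **batch means** over 50 contiguous batches: the
abundance series is strongly autocorrelated (the neutral chain decorrelates
over ~`N` updates, since each update touches one individual), so a naive
i.i.d. standard error would be badly optimistic. Batches of length
`\gg N` are effectively independent; 50 of them give a stable variance
estimate while remaining the single-run analogue of averaging independent
runs. The ergodicity of the chain is checked in the tests by agreement
between all-A and all-B initialisations.

Payoff accumulation comes in two schemes. Under `single_game` the focal
plays one game it organises. Under `averaged_d_games` (defined on regular
structures of degree `d - 1`, where every organiser's game has a
well-defined size) the focal's payoff is the average over the `d` games
organised by itself and each neighbour, so second neighbours matter. On
non-regular graphs the organiser's group size would vary and the averaged
scheme is deliberately rejected rather than silently redefined.

## What the generator emulates — and what it does not

The built-in experiment conditions mirror the simulation studies the
package is built around: three-player games (`d = 3`); ring populations of
`N = 100`; random (Erdős–Rényi, default edge probability `4/N`) and
scale-free (Barabási–Albert, `m = 2`) networks with a degree floor of 2 so
everyone can host a three-player game (generation is retried until
connected and repaired up to the floor — the floor is stated by the study
design, the enforcement mechanism is the package's choice); aspirations
homogeneous at 2, uniform on `[0, 1]` or `[0, 5]`, bimodal, or power-law;
initial A-fractions of 5% or 45%; selection intensities `\beta = 0.005`
(threshold-crossing experiments) and `\beta = 0.05` (regression
protocol). Where the original studies leave a parameter unstated (the ER
edge probability, the BA attachment count, the selection intensity of the
averaged-payoff comparison), the defaults above were fixed once, as
ordinary design choices, and are not tuned.

Synthetic aspirations are i.i.d. draws; real populations would likely show
spatial correlation between aspiration and network position, which nothing
here emulates. Passing tests therefore demonstrate the mathematical claims
about the model — not that any empirical population follows aspiration
dynamics.

## Problem sizes and power

Desk-scale replication cannot afford the original sample counts (up to
`1.5 \times 10^{10}` updates per data point). Budgets here are instead
sized from the exact first-order signal:

* **Threshold crossing** (`\beta = 0.005`, games one unit either side of
  the `a_0 = 2` boundary): predicted deviation `0.005/32 \approx 1.6
  \times 10^{-4}` on the ring. With the measured error scaling this needs
  `5 \times 10^8` updates per condition on the ring (expected separation
  ~5 SE) and `6 \times 10^8` on ER graphs. On BA graphs the measured
  deviation at `a_0 = 3` is smaller (~`9 \times 10^{-5}`) — degree
  heterogeneity makes the regular-network criterion only approximately
  applicable, consistent with the threshold being "approximately" 2 there —
  so that condition gets `1.2 \times 10^9` updates.
* **Coefficient regression**: 26 design points (`a_k \in \{-1, 0, 1\}`
  minus the all-zero game, `b \equiv 0`), `2 \times 10^6` post-burn-in
  updates each at `\beta = 0.05` on a ring of 100. The resulting 95%
  margins on the normalised ratios are ~0.3, comfortably resolving
  `(1, 2, 1)` and an intercept of 0.
* The exact-oracle checks (`N \le 8`, 256 states) run in milliseconds.

The regression reports *ratio-normalised* coefficients (`\hat\sigma_0
\equiv 1`, delta-method margins for the ratios): the criterion only
identifies `\sigma` up to a positive factor, and the raw response scale
(`\bar x - 1/2` per payoff unit) depends on `\beta`, `N` and `g'(0)`.

## Limitations

* The σ-rule is a weak-selection statement. Under strong selection the
  ranking can genuinely differ: individuals whose aspirations lie far below
  every payoff are always satisfied and act as zealots that never switch,
  while never-satisfied individuals churn symmetrically — so the initial
  composition of the low-aspiration group, not the criterion, decides the
  outcome. The package simulates this regime faithfully but the analytic
  machinery intentionally does not cover it.
* Decision functions are strategy-symmetric: an individual uses the same
  `g_i` whether it currently plays A or B. Strategy-dependent rules break
  the neutral-mutant symmetry and are out of scope.
* The exact solver is capped at `N = 14` and the averaged scheme at regular
  structures; non-regular averaged payoffs are undefined, not approximated.
* Directed, weighted and dynamically rewiring networks are not modelled.
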