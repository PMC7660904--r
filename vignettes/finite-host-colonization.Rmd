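---
title: "Methods: stochastic colonization of hosts with finite lifespans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic colonization of hosts with finite lifespans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finitehost)
```

## The process

`finitehost` models the assembly of a microbiome inside initially
microbe-free hosts as a discrete-time stochastic process. A host is a
habitat of fixed capacity `N`: every one of its `N` slots holds either a
microbe of one of `M` taxa or nothing. One time step is one microbial
death-birth event. A uniformly chosen slot is vacated and refilled from the
environment with probability `m` (proportionally to the pool frequencies
`p_i`; unoccupied space has pool frequency zero) or from the host itself
with probability `1 - m`, proportionally to the fitness-weighted local
frequencies `(1 + alpha_j) x_j`. Unoccupied space takes part in local
"reproduction" with weight `(1 + alpha_0) x_0`, so `alpha_0` tunes the
host's resistance to being filled: `alpha_0 < 0` means vacated slots are
reclaimed by microbes quickly. On top of this, each step carries a
probability `tau` of host death: the host is replaced by a microbe-free
newborn, which for the within-host state is a resetting of all microbial
frequencies to zero. Host lifespans are therefore geometric with mean
`(1 - tau) / tau` microbial events; `tau = 0` is the classical
infinite-lifespan neutral model, `tau = 1` hosts that die as fast as single
microbes.

Two views of this process are implemented and cross-checked throughout:

1. an **individual-based simulator** of the full multi-taxon kernel
   (any `alpha` permitted), and
2. a **marginal master equation** for one focal type at a time — a
   birth-death chain on the frequency grid `{0, 1/N, ..., 1}` augmented
   with a resetting flow `tau` from every state into the microbe-free
   state.

### Marginal closure

The marginal dynamics of one focal type is autonomous only if the local
reproduction weight can be written as a function of the focal frequency
alone. That holds in exactly two cases: the **empty-space marginal**
(`x_0`), where under taxon neutrality the denominator is
`(1 + alpha_0) x_0 + (1 - x_0)` for any `alpha_0`; and a **taxon marginal**
in the strictly neutral case `alpha_0 = 0`, all `alpha_i = 0`, where the
weights sum to one. For any other fitness configuration the package
deliberately refuses to build the marginal chain ("marginal closure
unavailable") instead of substituting an uncontrolled mean-field guess; the
individual-based simulator remains available there. This restriction
mirrors how the solver is actually used: every solver-based analysis either
targets empty space or is strictly neutral.

## Solving the stationary master equation

The one-step matrix is column-stochastic: `R = S + tau * e_r 1'`, with `S`
the tridiagonal survival part (its up/down/stay entries already carry the
survival factor `1 - tau`) and `e_r` the reset state — grid index 0 for a
taxon, `x_0 = 1` for empty space. Descriptions of reset-augmented chains
sometimes place the resetting probabilities in a *column* of the matrix;
under the column-vector convention used here that arrangement cannot be
column-stochastic, so the package fixes the orientation by the hard
constraint that columns of `R` sum to one: resetting is a row of inflow
`tau` into the reset state, which also contributes `tau` to the reset
state's own diagonal.

Rather than solving the eigenproblem `R phi = phi` with a dense
normalization row appended to `R - I` (which destroys the banded structure
and makes sparse LU orders of magnitude slower), the solver uses the
algebraic identity that under `sum(phi) = 1` stationarity is the **banded**
system `(S - I) phi = -tau e_r`. For `tau > 0`, `S - I` is strictly column
diagonally dominant (each column sum is exactly `-tau`), hence nonsingular
and an M-matrix: the solution is automatically non-negative and sums to one
in exact arithmetic. For `tau = 0` the generator is singular; its null
vector is found by pinning one reference state to 1, solving the
tridiagonal system and renormalizing, re-anchoring once at the mode of the
first attempt for conditioning. Absorbing corner cases at `tau = 0` (a
focal taxon with pool frequency 0 or 1, where one boundary absorbs) are
returned analytically as boundary point masses. Every solution is verified
against the full one-step matrix (`max |R phi - phi| < 1e-12` by default);
if the check fails the solver falls back to power iteration. Negative
entries from floating-point solves are clipped at zero and renormalized,
with a warning if the clip exceeds `1e-10`. In practice the direct solve
handles `tau` from `1e-9` to 1 at `N = 10^4` in milliseconds with residuals
near machine precision.

`propagate()` exposes the same matrix for transient dynamics and is used in
tests to confirm that long propagation and the direct solve agree
(total variation `< 1e-8` on a parameter lattice at `N <= 200`).

### The renewal identity

Because resetting erases all memory, the stationary law with resetting
equals the lifespan-weighted mixture of reset-free transients started from
the microbe-free state: `phi = sum_t tau (1 - tau)^t T0^t delta_reset`,
where `T0` is the `tau = 0` kernel. The discrete geometric weight
`tau (1 - tau)^t` (support starting at `t = 0`) replaces the exponential
lifespan density of the continuum description — it is the exact law of the
discrete-time chain, of which the exponential is the small-`tau` limit.
The tests assert this identity to total variation `1e-3` at a truncation
horizon of `20 / tau`, and the same logic underlies
`sample_at_host_death()`: trajectories are simulated *without* host death
and each host is observed at an independently drawn geometric lifespan,
which is also how simulations are compared to the solver.

## The diffusion approximation

For large `N` the chain is approximated by a Fokker-Planck equation with a
resetting source. Its drift and squared-noise coefficients are exposed as
standalone functions because they obey an exact algebraic identity with the
discrete kernel — `drift = (p_up - p_down) / N` and
`diffusion_sq = (p_up + p_down) / N^2` — which the tests assert to `1e-14`
on dense parameter grids; the same moments are verified independently by
brute-force enumeration of every (dying slot, replacement) outcome of the
one-step kernel at small `N`.

`stationary_fp()` discretizes the stationary equation with a conservative
flux-form central scheme (no-flux boundaries, resetting handled as a
source/sink pair, normalization replacing the redundant reset-state
balance row). The scheme choice is this package's own; it preserves total
mass by construction. The solver is intentionally second-class: as
`tau -> 0` the stationary law develops boundary spikes on the scale of
single grid cells, where a continuum approximation is unreliable, so the
function warns below `tau = 1e-6` and refuses to return silently
inconsistent output (it errors if substantial negative mass appears). The
master-equation solver is always the source of truth; the tests document
the diffusion solver's accuracy only relative to it (total variation
`< 0.05` at `tau = 1e-4`, `N = 10^3`).

## The simulator as synthetic-data generator

All data in this package are generated by the model itself; the simulator
doubles as the synthetic-data generator for every empirical comparison.
Its defaults follow the production configuration used throughout the
analyses: recording every 10 steps, initially sterile hosts (`x_0 = 1`),
two equally abundant pool taxa `p_1 = p_2 = 0.5` in the two-taxon
configurations, and 500 hosts at `N = 10^4` for production runs. Tests and
the shipped fast configs scale the same conditions down to `N = 100`-`200`
and 200-2000 hosts so the full suite runs in minutes; the Monte-Carlo
tolerances (e.g. total variation `< 0.1` between sampled simulations and
the solver at 2000 hosts) are set by the sampling error at those sizes.

Implementation choices worth knowing:

- **State storage** is the vector of counts `(n_0, ..., n_M)`, not per-slot
  arrays — the kernel only needs counts, and conservation `sum(n) = N` is
  asserted in tests at every recorded step.
- **Per-host RNG substreams** are derived from the master seed with
  L'Ecuyer-CMRG streams, so adding hosts never perturbs existing
  trajectories and runs are bit-reproducible. Within a host the draw order
  per step is fixed: death test, slot selection, replacement draw.
- **Host clocks are independent**: "time step" means one microbial event
  per host, matching a per-host definition of `tau`; hosts do not interact
  except through the constant pool.
- A **memory guard** refuses recording configurations beyond a configurable
  budget rather than exhausting RAM.

What the generator deliberately does *not* emulate — and hence what
agreement between simulator and solver does not establish about real data:
no vertical transmission (colonization is environmental only), a constant
colonizer pool, no host-to-host transmission, fixed capacity `N`, and no
taxon-specific selection in the solver comparisons. These are modelling
assumptions, not numerical approximations.

## Summary statistics and classification

- `total_variation()` implements the distribution-difference statistic
  `0.5 * sum |phi_a - phi_b|`, used to quantify the departure of
  finite-lifespan predictions from the `tau = 0` equilibrium; it is 0 only
  for identical distributions and 1 for disjoint support.
- `colonization_probabilities()` reads the boundary masses: for a taxon,
  absence `P[x < 1/N] = phi[0]` and full occupancy
  `P[x > (N-1)/N] = phi[1]`; for the empty-space marginal the roles swap
  (mass at `x_0 = 0` is the probability of hosts full of microbes; mass at
  `x_0 = 1`, hosts free of them).
- `classify_modality()` zeroes masses below `zero_threshold` (default
  `1e-9`, configurable) and then finds local maxima on the discrete grid.
  The grid-level maximum definition is unspecified in continuum treatments,
  so a deterministic, tie-stable rule is fixed here: strictly greater than
  both neighbours (one neighbour at the boundaries), with plateaus counting
  once at their first index. More than two surviving maxima — outside the
  at-most-bimodal taxonomy — returns the two largest with a `truncated`
  flag rather than an error. Classification is invariant to positive
  rescaling before normalization, and the exact edges of the bimodal region
  may shift by a small factor under a different maximum rule.

`find_bimodality_boundaries()` scans a log-spaced `tau` grid (at least 5
points per decade recommended), then refines each edge by bisection in
`log tau` against its nearest differently-classified neighbour to a 5%
relative tolerance by default — tight enough for the order-of-magnitude
claims made about the bimodality window, cheap enough to run at
`N = 10^4`. At that scale, with `m = 10^-3` and a single colonizer, the
scan brackets the window `tau ~ 8e-8` to `1.3e-6` (the acceptance tests
assert agreement with the reference range `7e-8` to `1e-6` within a factor
of two).

## Numerical choices, degenerate inputs, limitations

- Frequencies live on the exact integer grid `k/N`; no floating drift.
- Parameter validation is eager: `alpha <= -1`, out-of-range probabilities
  and non-conserving count vectors are rejected at construction.
- `tau = 0` with `m = 0` has absorbing boundaries and no unique stationary
  law; the solver raises an explicit error. Inside sweeps, per-cell solver
  failures are recorded in a `status` column and the sweep continues.
- Solver tolerances (`1e-12` residual; clip warning at `1e-10`) are
  engineering choices validated by the oracle properties in the test
  suite, not externally prescribed values.
- The joint multi-taxon master equation (state space of size `~N^M`) is out
  of scope; only marginals are solved exactly, which is sufficient because
  under neutrality every taxon's marginal is governed by the same
  single-type chain.
- Problem sizes in the default test run: solver checks at `N <= 200` plus
  spot checks at `N = 10^4`; simulation checks at `N = 100` with up to
  2000 hosts and 8000 steps. These sizes keep the suite fast while leaving
  the production scale exercised where the claims depend on it.
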