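# finitehost

Neutral models of host-associated microbiomes usually assume hosts live
forever, so the within-host community has time to settle at its long-term
equilibrium. Many real hosts do not: *C. elegans*, *D. melanogaster* and
*D. rerio* are born microbe-free, are colonized from the environment, and die
on a timescale comparable to that colonization. `finitehost` implements a
nearly-neutral stochastic model of this situation and the machinery to
interrogate it: it is aimed at microbial ecologists who want a null model for
partially colonized hosts, microbe-free individuals, and alternative
microbiome states ("enterotypes") that invokes no selection at all.

## The model

Each host holds `N` microbe-sized slots; `n_i` slots carry taxon `i`
(`i = 1..M`), and index 0 is reserved for unoccupied space,
`n_0 = N − Σ n_i`; frequencies are `x_i = n_i / N`. Per time step (one
microbial death-birth event) exactly one of four things happens to a focal
frequency:

```
P[x_i → 0 (host death)] = τ
P[x_i → x_i + 1/N]      = (1 − τ) (1 − x_i) [ m p_i + (1 − m) (1 + α_i) x_i / Σ_j (1 + α_j) x_j ]
P[x_i → x_i − 1/N]      = (1 − τ) x_i [ m (1 − p_i) + (1 − m) (1 − (1 + α_i) x_i / Σ_j (1 + α_j) x_j) ]
P[x_i → x_i]            = 1 − the rest
```

`m` is the probability that a vacated slot is filled by a migrant from a
fixed pool of colonizers with frequencies `p_i` (`p_0 = 0`: empty space never
immigrates); with probability `1 − m` the slot is refilled by local
reproduction weighted by fitness `(1 + α_j) x_j`. Empty space is a
pseudo-type whose weight `(1 + α_0) x_0` sets how fast hosts fill. `τ` is the
probability per microbial event that the host dies and is replaced by a
microbe-free newborn — a resetting ("catastrophe") of the chain to `x_i = 0`
(equivalently `x_0 = 1`), so host lifespans are geometrically distributed.

The package provides, as composable tidyverse-style functions:

- **Individual-based simulator** (`simulate_population()`, Rcpp core) of the
  full multi-taxon kernel with arbitrary fitness offsets, per-host RNG
  substreams, and tidy TSV trajectory export.
- **Master-equation solver** (`build_reset_chain()`,
  `stationary_distribution()`, `propagate()`): the exact `(N+1)`-state
  birth-death chain with resetting flow, solved as a banded linear system
  (fast and stable for `τ` from 1e-9 to 1).
- **Diffusion approximation** (`drift()`, `diffusion_sq()`,
  `stationary_fp()`): the Fokker-Planck drift/diffusion coefficients, exact
  kernel-moment identities, and a deliberately second-class finite-difference
  stationary solver.
- **Summary layer**: total-variation distance between finite- and
  infinite-lifespan predictions (`total_variation()`), colonization
  probabilities (`colonization_probabilities()`), modality classification of
  alternative microbiome states (`classify_modality()`), and
  lifespan-weighted sampling of simulated trajectories
  (`sample_at_host_death()`).
- **Parameter sweeps** (`sweep_config()`, `run_sweep()`,
  `find_bimodality_boundaries()`) over `(m, τ)` log-grids with manifests,
  plus a thin CLI (`inst/cli/finitehost.R`) and YAML configs under
  `inst/extdata/`.

## Worked example

A single colonizing taxon (`p_1 = 1`) at production scale `N = 10^4`, with
limited migration `m = 10^-3` and host death probability `τ = 3×10^-7`:

```r
library(finitehost)

pars  <- model_params(N = 1e4, m = 1e-3, tau = 3e-7, p = 1)
phi   <- stationary_distribution(build_reset_chain(focal_taxon(1), pars))
glance(phi)
#> # A tibble: 1 × 6
#>   n_states method          mean_frequency mass_at_0 mass_at_1 target_kind
#>      <int> <chr>                    <dbl>     <dbl>     <dbl> <chr>
#> 1    10001 master_equation          0.250  0.000333   0.00121 taxon

classify_modality(phi)
#> <modality_label> bimodal_0_and_1
#> # A tibble: 2 × 3
#>   state_index frequency     mass
#>         <int>     <dbl>    <dbl>
#> 1           0         0 0.000333
#> 2       10000         1 0.00121
```

The stationary distribution is bimodal with maxima at `x = 0` and `x = 1`:
microbe-free and fully colonized hosts coexist, purely because migration is
slow relative to the host lifespan — no selection involved. The mean
frequency (0.25) sits far from the pool frequency (1) that an
infinite-lifespan model would predict. Increasing `τ` to `10^-5` collapses
the distribution onto the microbe-free state (`unimodal_at_0`); decreasing it
to `10^-8` lets every host fill completely (`unimodal_at_1`).
`find_bimodality_boundaries()` locates the window of coexistence, and
`autoplot(phi)` draws the distribution.

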