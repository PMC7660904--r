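# Microbial-load phase map: empty-space marginal over an (m, tau) log grid
# at full production scale N = 10^4 (slow-occupation case alpha0 = 0).
N: 10000
m_grid: {from: 1.0e-4, to: 1.0, points_per_decade: 5}
tau_grid: {from: 1.0e-8, to: 1.0e-1, points_per_decade: 5}
targets:
  - kind: empty
    alpha0: 0
zero_threshold: 1.0e-9
seed: 1
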