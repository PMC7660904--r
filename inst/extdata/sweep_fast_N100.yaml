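# Desk-scale sweep (N = 100) for quick runs and continuous testing.
N: 100
m_grid: {from: 1.0e-3, to: 1.0e-1, points_per_decade: 2}
tau_grid: {from: 1.0e-4, to: 1.0e-1, points_per_decade: 2}
targets:
  - kind: taxon
    p_focal: 0.5
  - kind: empty
    alpha0: 0
zero_threshold: 1.0e-9
seed: 1
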