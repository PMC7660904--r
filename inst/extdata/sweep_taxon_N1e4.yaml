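# Single-colonizer phase map: taxon marginal with p = 1 at N = 10^4,
# the configuration whose tau cross-section shows the bimodality window.
N: 10000
m_grid: {from: 1.0e-4, to: 1.0, points_per_decade: 5}
tau_grid: {from: 1.0e-8, to: 1.0e-1, points_per_decade: 5}
targets:
  - kind: taxon
    p_focal: 1.0
zero_threshold: 1.0e-9
seed: 1
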