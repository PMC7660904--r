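# Desk-scale two-taxon colonization simulation: initially sterile hosts,
# equally abundant pool taxa, no host death in the trajectory (lifespan
# weighting is applied at sampling time).
N: 100
m: 0.01
tau: 0
p: [0.5, 0.5]
alpha0: 0
n_hosts: 200
n_steps: 6000
sample_every: 10
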