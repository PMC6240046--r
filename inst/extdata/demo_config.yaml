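workdir: tmrnet_demo
n_subjects: 6
grid:
- 12
- 12
- 12
n_parcels: 115
seed: 42
protocol: {}
truth: {}
behavior: {}
analysis:
  q: 0.05
  z_threshold: 2.33
  gamma: 1.0
  n_restarts: 100
  n_perm: 199
  connectivity: 6
  cutoff: 128
  ar1: estimate
seeds: {}
verbosity: 1
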