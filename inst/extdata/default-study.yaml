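# Default simulation study: four reference observers x four estimation
# procedures. Times in seconds throughout.
observers:
  - {lam: 0.470, gam: 7.5,  delta: 0.28}
  - {lam: 0.450, gam: 5.0,  delta: 0.22}
  - {lam: 0.495, gam: 22.0, delta: 0.24}
  - {lam: 0.495, gam: 20.0, delta: 0.36}
procedures:
  - {procedure: 1, total_trials: 2048, block_length: 16}
  - {procedure: 2, total_trials: 2048, block_length: 16}
  - {procedure: 3, total_trials: 2048, block_length: 16}
  - {procedure: 4, total_trials: 2048, block_length: 16}
n_reps: 200
master_seed: 1
eval:
  precision_threshold: 0.02
  hwci_level: 0.682
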