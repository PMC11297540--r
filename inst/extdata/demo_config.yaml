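# Demo configuration for the command-line wrapper.
# All sim_config() fields may appear here; spc: and model: blocks are
# passed to the lookback builder and the quantile-regression layer.
n_patients: 5000
seed: 2026
model:
  taus: [0.5, 0.9]
  B: 200
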