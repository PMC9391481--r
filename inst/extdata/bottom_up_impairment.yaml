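# Bottom-up information impairment: every perceiving neuron keeps a random
# 1050 of its 2100 incoming connections from the visual and memory modules
# (pooled budget; the per-source split fluctuates around the module sizes).
experiment: bottom_up_impairment
seeds:
  patterns: 101
  lesion: 202
  noise: 303
lesion:
  pooled:
    - {target: P, sources: [V, M], r: 1050}
run:
  steps: 100
  n_config: 20
  n_probe: 11
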