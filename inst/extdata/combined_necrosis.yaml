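# Combined necrosis "typical case" protocol: visual-module cell death plus
# pruning of the visual outflow pathways (V->M and V->P), with the
# perceiving-memory projections left intact. Repeated random configurations
# at the same severity decide whether an outcome is "typical" (frequency
# >= 0.5 across configurations).
experiment: combined_necrosis
seeds:
  patterns: 101
  lesion: 202
  noise: 303
lesion:
  dead: {V: 90}
  fan_in:
    M<-V: 630
    P<-V: 630
run:
  steps: 100
  n_config: 10
  n_probe: 11
classify:
  typical_threshold: 0.5
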