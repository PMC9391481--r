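# Neuromodulator-impairment stand-in: slow sinusoidal threshold on the
# perceiving module, theta_P(t) = 0.02 * sin(2*pi*t/100), probed at every
# onset phase of one modulation period. The accompanying lesion (pooled
# bottom-up budget 700 of 2100) puts recall in the marginal regime where a
# 0.02 threshold shift can tip the outcome; on an intact network every
# local field on the attractor is exactly +-1, so the modulation is inert.
experiment: threshold_fluctuation
seeds:
  patterns: 101
  lesion: 202
  noise: 303
schedule:
  P: {A: 0.02, period: 100}
lesion:
  pooled:
    - {target: P, sources: [V, M], r: 700}
run:
  steps: 100
  n_probe: 3
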