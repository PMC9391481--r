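# pasim

Simulation of veridical perception — and its breakdown into
hallucination-like states — in a three-module binary attractor network.

## The scientific problem

Recurrent complex visual hallucinations in dementia with Lewy bodies have
been interpreted through the destabilization of the cortical attractor
dynamics that normally settle incoming stimuli onto a stable percept.
`pasim` implements that hypothesis as a concrete, testable network model
for computational neuroscientists: a binary recurrent network with a
visual (V), memory (M) and perceiving (P) module whose memories are
*perceiving attractors* — limit cycles in which the visual and memory
modules run through `L = 10` patterns per cycle while the perceiving
module holds one fixed pattern (a many-to-one map from images to a
percept). Disease enters as neuron death, random pruning of incoming
synaptic connections, and slow sinusoidal threshold fluctuations standing
in for impaired neuromodulator release; the package measures what these do
to recall.

## The model

State vector `s(t) ∈ {−1,+1}^N` (default `N = 3000`: 900 + 1200 + 900),
updated synchronously:

```
s_i(t+1) = sgn( Σ_j ε_ij w_ij s_j(t) + q_i δ_{i∈V} − θ_i(t) ),   sgn(u ≥ 0) = +1
```

Weights embed `K = 11` cycles of period `L = 10` by the pseudo-inverse
(orthogonalized) rule: with patterns as columns of `X`, overlap matrix
`O = XᵀX` and adjoints `D = X O⁻¹`,

```
w = X_next Dᵀ        so that   w ξ^(μ,λ) = ξ^(μ,λ+1)   exactly.
```

`ε` is the binary connectivity mask: a dead neuron zeroes its row and
column; a pruned projection keeps exactly `r` incoming connections per
living target neuron (the bottom-up-impairment scenario keeps a pooled
`r(P←V) + r(P←M) = 1050` of 2100). Each probe run is classified as
`veridical`, `transient-error-then-veridical`, `hallucination-like`, or
`non-convergent` from the perceiving module's overlap with the `K`
embedded percepts over time.

## Worked example

```r
library(pasim)

layout <- module_layout()                      # 900 + 1200 + 900 neurons
ps <- generate_patterns(layout, K = 11, L = 10, seed = 101)
w  <- build_weights(ps, compute_adjoints(ps))

# a 5%-corrupted stimulus for cycle 3, perceiving module uncommitted
probe <- noisy_probe(ps, mu = 3, flip_frac = 0.05, seed = 303,
                     perceiving = "random")
traj <- run_simulation(probe, steps = 100, w)
traj
#> Trajectory: 100 steps, N=3000, period 10 from step 2
classify_outcome(traj, ps, input_cycle = 3)
#> Outcome: veridical (probe cycle 3 -> final 3)
```

The intact network falls onto the probed cycle's orbit within two steps
(detected period 10 = the embedding period), i.e. veridical perception.
Now halve the perceiving module's bottom-up fan-in and sweep random
lesion configurations:

```r
sw <- run_bottom_up_impairment(ps, w, budget = 1050, n_config = 20, seed = 1)
sw
#> Sweep (bottom_up_impairment): 220 runs
#>   veridical                        96.4%
#>   transient-error-then-veridical    0.9%
#>   hallucination-like                0.0%
#>   non-convergent                    2.7%
```

Most probes still converge veridically, a fraction shows sustained
erroneous perception before self-correcting, and some runs never settle —
the destabilization regime the lesion scenarios study. Threshold
fluctuations (`run_threshold_fluctuation()`, canonical schedule
`θ_P = 0.02·sin(2πt/100)`) and combined necrosis grids
(`run_combined_necrosis()`) follow the same pattern; ready-made configs
ship under `inst/extdata/` and the methods vignette
(`vignettes/perceiving-attractors.Rmd`) documents every modelling choice.

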