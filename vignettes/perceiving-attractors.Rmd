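---
title: "Perceiving attractors: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceiving attractors: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasim)
```

## The model

`pasim` simulates a binary recurrent network of `N` neurons split into a
visual (V), memory (M) and perceiving (P) module. The state is a vector
`s(t)` with entries ±1 ("active"/"non-active"), updated synchronously:

    s_i(t+1) = sgn( sum_j eps_ij w_ij s_j(t) + q_i [i in V] - theta_i(t) )

with the convention `sgn(u) = +1` for `u >= 0`. Here `w` is the synaptic
matrix, `eps` a binary connectivity mask encoding pathology, `q` an
external input restricted to the visual module, and `theta` a per-module
threshold standing in for neuromodulatory tone. At the default layout the
modules hold 900, 1200 and 900 neurons (visualized as 30×30, 30×40 and
30×30 bit grids), so `N = 3000`.

The memories are `K = 11` **limit cycles of period `L = 10`**: within
cycle `mu` the visual and memory blocks run through 10 distinct patterns
`xi^(mu,1) … xi^(mu,10)` (cyclically closed), while the perceiving block
holds one fixed pattern for the whole cycle. This many-to-one
("ten-to-one") structure is the model's metaphor for concept formation: many
retinal images, one percept. A stable percept is the network orbiting one
of these cycles — a *perceiving attractor*.

### Pseudo-inverse learning

Weights are built so the cycles are *exact* orbits of the sign update.
Collecting the `K·L` patterns as columns of `X`, the overlap matrix is
`O = XᵀX` and the adjoint (dual) vectors are the columns of `D = X O⁻¹`,
which satisfy `Dᵀ X = I`. The weight matrix

    w = X_next Dᵀ,   X_next = X with columns advanced one phase

then gives `w xi^(mu,lambda) = xi^(mu,lambda+1)` exactly in real
arithmetic, hence exactly under `sgn`. Two consequences shape everything
downstream:

* **capacity** — the construction needs linearly independent patterns,
  generic for random ±1 patterns when `K·L ≪ N`. The generator enforces
  `K·L ≤ N/4` and `compute_adjoints()` treats an overlap condition number
  above `1e8` as a degenerate pattern set (error, never silent
  regularization). At the default loading (110 patterns in 3000
  dimensions) the condition number is ~2.
* **exactly ±1 local fields on the attractor** — on an embedded state
  every neuron's field is exactly the next pattern value, ±1. A small
  threshold (the canonical impairment amplitude is 0.02) therefore cannot
  destabilize an intact attractor; threshold fluctuations only matter once
  lesions have shrunk the field margins. This is why the
  threshold-fluctuation experiment ships with a lesion (below).

Adjoints are computed over the full concatenated `N`-vectors — one global
pseudo-inverse — and the nine module-to-module blocks `w^(kappa,eta)` are
read off the single matrix. Computing per-module pseudo-inverses instead
would not make the three-module cycles exact attractor states.

## Pathology encoding

* **Necrosis** — a dead neuron's entire row and column of `eps` are
  zeroed: it receives nothing and influences nothing. Its state is clamped
  to −1 and it is excluded from overlap normalization; with zero fan-in the
  raw update would return `sgn(-theta)`, a threshold-sign artefact with no
  physiological meaning for a dead cell.
* **Fan-in pruning** — only incoming connections are pruned. Each living
  target neuron of a constrained projection keeps exactly `r` survivors
  drawn uniformly without replacement. A *pooled* budget (the
  bottom-up-impairment case `r(P←V) + r(P←M) = 1050` of 2100) draws the
  survivors from the pooled candidate set, so the per-source split
  fluctuates around the module-size ratio (~450:600); the constraint in the
  scenario is the sum, and nothing fixes the split.
* **Threshold fluctuation** — `theta^kappa(t) = A sin(2π(t + phase)/T)`
  uniformly within a module; the canonical perceiving-module schedule is
  `A = 0.02`, `T = 100` steps. Thresholds are module-wide scalars: the
  update rule indexes `theta` per neuron, but the scenarios only ever
  specify one schedule per module.

## Probes and outcome classification

A recall probe starts from the embedded state `(mu, 1)` with
`flip_frac = 0.05` of the visual bits flipped (default; exposed in every
runner). The perceiving block of the probe is **random** in the scenario
runners: perception means *forming* the percept from the bottom up, and a
probe that starts the perceiving module on the answer cannot, by
construction, show the initial erroneous perception the lesion scenarios
are about. For basin-geometry questions (`noisy_probe(..., perceiving =
"pattern")`, used by the recall-robustness checks) the probe is instead a
bona-fide point near the attractor. The memory block starts on-pattern:
the memory trace itself is not the diseased component in these scenarios.

Each step, the perceiving state is compared by overlap (on living P
neurons) with the `K` perceiving patterns; overlap ≥ `match_threshold`
(default 0.95) counts as a match. With `sustain = L` (default):

* **veridical** — the final `L` steps all match the probed cycle, with no
  earlier `L`-step window failing to match it;
* **transient-error-then-veridical** — veridical ending, but some earlier
  `L` consecutive steps did not match the probe (sustained erroneous
  perception that self-corrected);
* **hallucination-like** — some `L`-step window matches a single *other*
  cycle, without a veridical ending;
* **non-convergent** — none of the above.

The rules are tested in that order, so every trajectory gets exactly one
label. The defaults were chosen so that exact-orbit entry always counts as
veridical and an excursion shorter than one cycle period never flips a
label; 0.95 lies far above chance overlap (`O(1/sqrt(900)) ≈ 0.03`) and
below the smallest on-attractor overlap after a single-bit error
(1 − 2/900 ≈ 0.998). A mid-run sustained match to another cycle followed
by recovery counts as transient error, not hallucination: the end state
wins.

Cycle/convergence detection in single runs is exact state repetition —
binary states make tolerance-free detection correct — reporting the
smallest period and earliest onset.

## The scenario runners

All sweeps derive every lesion and noise seed deterministically from one
master seed and carry the full seed manifest in their result, so any run
is reproducible from its summary.

* `run_bottom_up_impairment()` — pooled P fan-in budget; the canonical
  impaired value 1050 of 2100. At that budget the intact-control basin is
  untouched (the control sweep is 100% veridical) while probes that must
  form the percept occasionally err for a sustained stretch before
  converging veridically, and a minority stick or hallucinate.
* `run_threshold_fluctuation()` — probes one fixed noisy stimulus at every
  onset phase of the modulation (default `0:(T−1)`). The shipped example
  lesion is a pooled budget of 700: recall there is *marginal*, so the
  ±0.02 threshold swing tips outcomes and the label becomes a function of
  onset phase. At 1050 the margins (~0.3) dwarf the amplitude and the
  modulation is provably inert; this is a property of pseudo-inverse
  learning with uncorrelated random patterns, not a bug.
* `run_combined_necrosis()` — a named grid of lesion configurations, each
  re-drawn over `n_config` random configurations; a label occurring with
  frequency ≥ `typical_threshold` (default 0.5, over ≥10 configurations
  recommended) flags the cell as a "typical case". The shipped example
  config combines visual-module necrosis (90 of 900 cells) with pruning of
  the visual outflow (V→M, V→P at 630 of the living 810) and an intact
  P↔M pathway.

## What the synthetic patterns do and do not emulate

The generator draws i.i.d. equiprobable ±1 patterns (rejection-resampling
any collision, so distinctness is guaranteed even at toy sizes). Real
stimuli — and the pictorial bit patterns the scenarios are meant to evoke —
are *correlated*, which lowers effective capacity, shrinks field margins
and lengthens transients. Random patterns therefore make the model
*more* robust than a pictorial embedding at the same size: destabilization
thresholds here (e.g. the budget at which threshold fluctuations bite) are
conservative, and passing tests demonstrate the mechanisms, not
quantitative lesion thresholds for any real stimulus set. Users can swap
in their own bitmaps via the PBM interface (`read_patterns()`), provided
the per-cycle structure (distinct V/M patterns, one fixed P pattern) is
respected.

## Numerical choices and degenerate inputs

* `sgn(0) = +1`, exactly as the update rule defines it; the all-zero-field
  state maps to all-active.
* The overlap-matrix solve is dense (`solve(O)`), no regularization;
  110×110 at default size.
* Weight build, probe batches and sweeps are plain dense BLAS operations;
  a sweep runs all probes of one mask as columns of a single matrix
  product per step, and stops early once every column exactly repeats its
  state `L` steps earlier (the continuation is then cyclic and exact),
  which is what keeps 50-configuration sweeps to minutes.
* `K = L = 1` embeds a single fixed point; all operations, including
  cycle detection (period 1), handle it.
* Problem sizes used by the shipped checks: the full default network
  (N = 3000, 110 patterns) for attractor-exactness, recall (200 probes)
  and the sweeps (60/50/20 configurations × 11 probes, 100-step runs);
  N = 300 scaled replicas for the unit and property tests.

## Known limitations

* No asynchronous or stochastic (finite-temperature) update variant.
* Fan-out pruning is not implemented (scenarios specify fan-in only).
* Chaotic itinerancy at deep dilution is only *observed* (as
  non-convergent labels); no itinerancy statistics are computed.
* The clinical interpretation layer — hallucination frequency in patients,
  imaging correlates — is outside the model: the package computes network
  outcomes, nothing more.
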