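Package: pasim
Title: Limit-Cycle Attractor Network Simulation of Veridical and
    Hallucination-Like Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator for a three-module (visual, memory, perceiving)
    binary recurrent network in which veridical perception is modelled as
    convergence onto embedded limit-cycle "perceiving attractors" and
    hallucination-like states arise when those attractors are destabilized.
    Weight matrices are built by the pseudo-inverse (orthogonalized)
    learning rule so that cyclic pattern sequences are exact orbits of the
    synchronous sign-function update. Disease is encoded as neuron death
    (zeroed rows and columns of a binary connectivity mask), random fan-in
    pruning per projection, and slow sinusoidal threshold fluctuations
    standing in for impaired neuromodulator release. Includes scenario
    runners that probe lesioned networks with noisy visual input, classify
    outcomes (veridical, transient-error-then-veridical,
    hallucination-like, non-convergent), and sweep lesion severities over
    repeated random configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
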