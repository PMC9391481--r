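# Shared scaled-down fixtures. Built once per test run; every stochastic
# draw is seeded so the suite is deterministic.

tiny_layout <- function() module_layout(9, 12, 9)

small_layout <- function() module_layout(90, 120, 90)

# A small embedded network (K = 3 cycles of period L = 4, N = 300),
# memoized across test files.
small_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ps <- generate_patterns(small_layout(), K = 3, L = 4, seed = 42)
      adj <- compute_adjoints(ps)
      cache <<- list(ps = ps, adj = adj, w = build_weights(ps, adj))
    }
    cache
  }
})

# Proportion of living incoming connections per living target neuron,
# counted directly from the mask (the brute-force fan-in oracle).
realized_fan_in <- function(mask, targets, sources) {
  living_t <- setdiff(targets, mask$dead)
  living_s <- setdiff(sources, mask$dead)
  rowSums(mask$eps[living_t, living_s, drop = FALSE])
}
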