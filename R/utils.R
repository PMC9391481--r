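# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream of sub-seeds for the independent stochastic
# components of an experiment (lesion draws, probe noise, ...).
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(2147483646L, n))
}

# Cheap deterministic checksum tying adjoints/weights to their pattern set.
pattern_checksum <- function(ps) {
  x <- ps$xi
  w <- rep_len(c(1, 3, 7, 13, 31, 57), length(x))
  sprintf("%dx%dx%d:%.0f", ps$K, ps$L, nrow(x), sum(x * w) %% 1e15)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
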