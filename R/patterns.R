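#' Generate a set of limit-cycle attractor patterns
#'
#' Draws the `K * L` binary state vectors that the learning rule will embed
#' as `K` limit cycles of period `L`. Within each cycle mu the visual and
#' memory blocks run through `L` pairwise-distinct patterns, while the
#' perceiving block holds one fixed pattern for the whole cycle — the
#' many-to-one ("ten-to-one" at the default `L = 10`) correspondence that
#' stands in for a stable percept. The `K` perceiving patterns are pairwise
#' distinct across cycles.
#'
#' Entries are i.i.d. equiprobable plus/minus 1; any colliding block is
#' rejection-resampled so the distinctness invariants hold even for tiny
#' layouts. The loading `K * L` must stay well below the network size
#' (enforced as `K * L <= N / 4`) for the pseudo-inverse construction to be
#' well conditioned.
#'
#' @param layout A [module_layout()].
#' @param K Number of cycles.
#' @param L Period (steps) of each cycle.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return A `pattern_set`: list with `layout`, `K`, `L`, `seed` and `xi`,
#'   an `N x (K*L)` matrix whose column `(mu - 1) * L + lambda` holds the
#'   state vector of cycle `mu`, phase `lambda`.
#' @examples
#' ps <- generate_patterns(module_layout(9, 12, 9), K = 2, L = 3, seed = 7)
#' dim(ps$xi)  # 30 x 6
#' @export
generate_patterns <- function(layout, K, L, seed) {
  stopifnot(inherits(layout, "module_layout"))
  K <- as.integer(K); L <- as.integer(L)
  if (K < 1L || L < 1L)
    stop("K and L must be >= 1", call. = FALSE)
  N <- layout_total(layout)
  if (K * L > N / 4)
    stop(sprintf("capacity error: K*L = %d exceeds N/4 = %.0f; use fewer or shorter cycles",
                 K * L, N / 4), call. = FALSE)
  rng <- module_ranges(layout)
  xi <- local_seed(seed, {
    x <- matrix(0, N, K * L)
    for (mu in seq_len(K)) {
      cols <- (mu - 1L) * L + seq_len(L)
      x[rng$V, cols] <- distinct_pm1(layout$n_visual, L)
      x[rng$M, cols] <- distinct_pm1(layout$n_memory, L)
    }
    # one fixed perceiving pattern per cycle, distinct across cycles
    pk <- distinct_pm1(layout$n_perceiving, K)
    for (mu in seq_len(K))
      x[rng$P, (mu - 1L) * L + seq_len(L)] <- pk[, mu]
    x
  })
  structure(list(layout = layout, K = K, L = L, xi = xi,
                 seed = as.integer(seed)),
            class = "pattern_set")
}

# n x m matrix of +-1 with pairwise-distinct columns (rejection resampling).
distinct_pm1 <- function(n, m) {
  x <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
  repeat {
    dup <- duplicated(apply(x, 2L, paste, collapse = ""))
    if (!any(dup)) break
    x[, dup] <- sample(c(-1, 1), n * sum(dup), replace = TRUE)
  }
  x
}

#' Column index of cycle `mu`, phase `lambda` in a pattern matrix
#'
#' Phases advance cyclically: the successor of `(mu, L)` is `(mu, 1)`.
#' @param mu,lambda Cycle and phase (1-based).
#' @param L Period of the cycles.
#' @export
pattern_index <- function(mu, lambda, L) (mu - 1L) * L + lambda

# Column indices of the one-phase-advanced targets, in source order.
successor_index <- function(K, L) {
  as.vector(vapply(seq_len(K), function(mu)
    pattern_index(mu, c(seq_len(L - 1L) + 1L, 1L), L), integer(L)))
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("Pattern set: K=%d cycles x L=%d steps, N=%d (seed %d)\n",
              x$K, x$L, nrow(x$xi), x$seed))
  invisible(x)
}

#' Serialize / load a pattern set
#'
#' Each visual and memory block is written as one ASCII PBM (P1) bitmap per
#' cycle and phase, the fixed perceiving block as one bitmap per cycle, with
#' the map +1 -> 1 (active), -1 -> 0. A `patterns.json` manifest records the
#' layout, `K`, `L`, seed and file list. `read_patterns()` is the exact
#' inverse: the round trip is bit-exact.
#'
#' @param ps A `pattern_set`.
#' @param path Directory to write into (created if missing).
#' @return `write_patterns()` returns the manifest path invisibly;
#'   `read_patterns()` returns the reconstructed `pattern_set`.
#' @export
write_patterns <- function(ps, path) {
  stopifnot(inherits(ps, "pattern_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  lay <- ps$layout
  rng <- module_ranges(lay)
  files <- list(V = character(0), M = character(0), P = character(0))
  for (mu in seq_len(ps$K)) {
    for (lambda in seq_len(ps$L)) {
      j <- pattern_index(mu, lambda, ps$L)
      fv <- sprintf("v_mu%02d_l%02d.pbm", mu, lambda)
      fm <- sprintf("m_mu%02d_l%02d.pbm", mu, lambda)
      write_pbm(ps$xi[rng$V, j], lay$visual_grid, file.path(path, fv))
      write_pbm(ps$xi[rng$M, j], lay$memory_grid, file.path(path, fm))
      files$V <- c(files$V, fv); files$M <- c(files$M, fm)
    }
    fp <- sprintf("p_mu%02d.pbm", mu)
    write_pbm(ps$xi[rng$P, pattern_index(mu, 1L, ps$L)],
              lay$perceiving_grid, file.path(path, fp))
    files$P <- c(files$P, fp)
  }
  manifest <- list(n_visual = lay$n_visual, n_memory = lay$n_memory,
                   n_perceiving = lay$n_perceiving,
                   grids = list(V = lay$visual_grid, M = lay$memory_grid,
                                P = lay$perceiving_grid),
                   K = ps$K, L = ps$L, seed = ps$seed, files = files)
  mpath <- file.path(path, "patterns.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  mpath <- file.path(path, "patterns.json")
  if (!file.exists(mpath))
    stop("format error: no patterns.json manifest in ", path, call. = FALSE)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  lay <- module_layout(man$n_visual, man$n_memory, man$n_perceiving,
                       man$grids$V, man$grids$M, man$grids$P)
  K <- as.integer(man$K); L <- as.integer(man$L)
  rng <- module_ranges(lay)
  xi <- matrix(0, layout_total(lay), K * L)
  read_block <- function(file, grid) {
    v <- read_pbm(file.path(path, file))
    if (!identical(attr(v, "grid"), as.integer(grid)))
      stop(sprintf("format error: %s is %s but manifest says %s", file,
                   paste(attr(v, "grid"), collapse = "x"),
                   paste(grid, collapse = "x")), call. = FALSE)
    as.numeric(v)
  }
  for (mu in seq_len(K)) {
    p_block <- read_block(man$files$P[mu], lay$perceiving_grid)
    for (lambda in seq_len(L)) {
      j <- pattern_index(mu, lambda, L)
      k <- (mu - 1L) * L + lambda
      xi[rng$V, j] <- read_block(man$files$V[k], lay$visual_grid)
      xi[rng$M, j] <- read_block(man$files$M[k], lay$memory_grid)
      xi[rng$P, j] <- p_block
    }
  }
  structure(list(layout = lay, K = K, L = L, xi = xi,
                 seed = as.integer(man$seed)),
            class = "pattern_set")
}
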