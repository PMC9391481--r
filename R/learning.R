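#' Adjoint (dual) vectors of a pattern set
#'
#' Computes the adjoint vectors used by the pseudo-inverse (orthogonalized)
#' learning rule. With the patterns collected as columns of the `N x (K*L)`
#' matrix `X`, the overlap matrix is `O = t(X) X` (entries
#' `o = sum_j xi_j^{mu,lambda} xi_j^{alpha,beta}`, diagonal `N`) and the
#' adjoints are the columns of `D = X O^{-1}`, so that
#' `t(D) X = I`: each adjoint has unit inner product with its own pattern
#' and zero with every other, which is what makes the embedded transitions
#' exact under the sign update.
#'
#' The overlap matrix is inverted by a dense solve with no regularization;
#' random patterns with `K*L << N` are generically well conditioned, and an
#' ill-conditioned overlap (2-norm condition number above `1e8`) is treated
#' as a degenerate pattern set rather than silently repaired.
#'
#' @param ps A `pattern_set` from [generate_patterns()].
#' @return An `adjoint_set`: list with `dagger` (`N x (K*L)` matrix of
#'   adjoint vectors), `overlap`, `overlap_inverse`, `condition_number`, and
#'   a checksum tying it to `ps`.
#' @seealso [build_weights()]
#' @export
compute_adjoints <- function(ps) {
  stopifnot(inherits(ps, "pattern_set"))
  X <- ps$xi
  O <- crossprod(X)
  cn <- kappa(O, exact = TRUE)
  if (!is.finite(cn) || cn > 1e8)
    stop(sprintf(paste0("degeneracy error: pattern overlap matrix has ",
                        "condition number %.3g (> 1e8); the patterns are ",
                        "(nearly) linearly dependent — regenerate with a ",
                        "different seed or lower K*L"), cn), call. = FALSE)
  Oinv <- solve(O)
  structure(list(dagger = X %*% Oinv, overlap = O, overlap_inverse = Oinv,
                 condition_number = cn, checksum = pattern_checksum(ps)),
            class = "adjoint_set")
}

#' Build the synaptic weight matrix embedding the limit cycles
#'
#' Pseudo-inverse learning: `w = sum_{mu,lambda} xi^{mu,lambda+1} (dagger
#' xi^{mu,lambda})^T`, with cyclic closure `xi^{mu,L+1} = xi^{mu,1}`. By
#' the adjoint orthonormality, `w xi^{mu,lambda} = xi^{mu,lambda+1}`
#' holds exactly in exact arithmetic, so every embedded sequence is an
#' exact orbit of the synchronous sign update at full connectivity.
#'
#' The matrix is built over the full concatenated state space; the
#' intra/inter-module blocks `w^{(kappa,eta)}` of the three-module update
#' are read off this one global matrix via `block_index`.
#'
#' @param ps The `pattern_set` the adjoints were computed from.
#' @param adj The matching `adjoint_set`.
#' @return A `weight_matrix`: list with the `N x N` matrix `w`, a
#'   `block_index` mapping each (target, source) module pair to its row and
#'   column ranges, the `layout`, `K`, `L` and the pattern-set checksum.
#' @export
build_weights <- function(ps, adj) {
  stopifnot(inherits(ps, "pattern_set"), inherits(adj, "adjoint_set"))
  if (!identical(adj$checksum, pattern_checksum(ps)))
    stop("consistency error: adjoint set was not computed from this pattern set",
         call. = FALSE)
  succ <- successor_index(ps$K, ps$L)
  w <- ps$xi[, succ, drop = FALSE] %*% t(adj$dagger)
  rng <- module_ranges(ps$layout)
  block_index <- list()
  for (target in names(rng))
    for (source in names(rng))
      block_index[[paste0(target, "<-", source)]] <-
        list(rows = rng[[target]], cols = rng[[source]])
  structure(list(w = w, block_index = block_index, layout = ps$layout,
                 K = ps$K, L = ps$L, checksum = adj$checksum),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("Weight matrix: %d x %d, embedding K=%d cycles of period L=%d\n",
              nrow(x$w), ncol(x$w), x$K, x$L))
  invisible(x)
}

#' @export
print.adjoint_set <- function(x, ...) {
  cat(sprintf("Adjoint set: %d vectors of length %d (overlap condition number %.3g)\n",
              ncol(x$dagger), nrow(x$dagger), x$condition_number))
  invisible(x)
}

#' Persist / load a weight matrix
#'
#' The matrix is stored as raw little-endian doubles (column-major) next to
#' a JSON sidecar holding the dimensions, layout, `K`, `L` and the
#' pattern-set checksum; `read_weights()` verifies the checksum against a
#' pattern set when one is supplied.
#'
#' @param wm A `weight_matrix`.
#' @param path Basename for the pair `<path>.bin` / `<path>.json`.
#' @param ps Optional `pattern_set` to verify the checksum against.
#' @export
write_weights <- function(wm, path) {
  stopifnot(inherits(wm, "weight_matrix"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(wm$w), con, size = 8L, endian = "little")
  lay <- wm$layout
  jsonlite::write_json(
    list(n = nrow(wm$w), K = wm$K, L = wm$L, checksum = wm$checksum,
         layout = list(n_visual = lay$n_visual, n_memory = lay$n_memory,
                       n_perceiving = lay$n_perceiving)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path, ps = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- as.integer(meta$n)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  w <- matrix(readBin(con, "double", n * n, size = 8L, endian = "little"), n, n)
  lay <- module_layout(meta$layout$n_visual, meta$layout$n_memory,
                       meta$layout$n_perceiving)
  if (!is.null(ps) && !identical(meta$checksum, pattern_checksum(ps)))
    stop("consistency error: stored weights do not match this pattern set",
         call. = FALSE)
  rng <- module_ranges(lay)
  block_index <- list()
  for (target in names(rng))
    for (source in names(rng))
      block_index[[paste0(target, "<-", source)]] <-
        list(rows = rng[[target]], cols = rng[[source]])
  structure(list(w = w, block_index = block_index, layout = lay,
                 K = as.integer(meta$K), L = as.integer(meta$L),
                 checksum = meta$checksum),
            class = "weight_matrix")
}
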