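#' Module layout of the three-module network
#'
#' Defines the neuron counts of the visual (V), memory (M) and perceiving (P)
#' modules together with the rectangular bit-pattern grids used to visualize
#' each module's state. State vectors concatenate the modules in the fixed
#' order V, M, P, so the full network dimension is
#' `N = n_visual + n_memory + n_perceiving`.
#'
#' The defaults (900, 1200, 900 neurons displayed as 30x30, 30x40 and 30x30
#' grids) are the configuration used throughout the shipped experiments.
#'
#' @param n_visual,n_memory,n_perceiving Neuron counts per module.
#' @param visual_grid,memory_grid,perceiving_grid Integer `c(rows, cols)`
#'   display grids; `rows * cols` must equal the module's neuron count. When
#'   `NULL`, the most nearly square factorization is chosen.
#' @return An object of class `module_layout`.
#' @examples
#' module_layout()                 # the default 3000-neuron network
#' module_layout(9, 12, 9)         # a toy layout for quick experiments
#' @export
module_layout <- function(n_visual = 900, n_memory = 1200, n_perceiving = 900,
                          visual_grid = NULL, memory_grid = NULL,
                          perceiving_grid = NULL) {
  counts <- c(V = n_visual, M = n_memory, P = n_perceiving)
  if (any(counts < 1) || any(counts != as.integer(counts)))
    stop("module neuron counts must be positive integers", call. = FALSE)
  grids <- list(V = visual_grid, M = memory_grid, P = perceiving_grid)
  for (m in names(grids)) {
    g <- grids[[m]] %||% near_square_grid(counts[[m]])
    g <- as.integer(g)
    if (length(g) != 2L || prod(g) != counts[[m]])
      stop(sprintf("grid for module %s is %s but must multiply to %d",
                   m, paste(g, collapse = "x"), counts[[m]]), call. = FALSE)
    grids[[m]] <- g
  }
  structure(list(n_visual = as.integer(n_visual),
                 n_memory = as.integer(n_memory),
                 n_perceiving = as.integer(n_perceiving),
                 visual_grid = grids$V, memory_grid = grids$M,
                 perceiving_grid = grids$P),
            class = "module_layout")
}

near_square_grid <- function(n) {
  r <- max(which(n %% seq_len(floor(sqrt(n))) == 0))
  c(r, n %/% r)
}

#' Total neuron count of a layout
#' @param layout A [module_layout()].
#' @return Integer `N`.
#' @export
layout_total <- function(layout) {
  layout$n_visual + layout$n_memory + layout$n_perceiving
}

#' Neuron index ranges of the three modules
#'
#' @param layout A [module_layout()].
#' @return Named list with integer index vectors `V`, `M`, `P` into the
#'   concatenated state vector.
#' @export
module_ranges <- function(layout) {
  nv <- layout$n_visual; nm <- layout$n_memory; np <- layout$n_perceiving
  list(V = seq_len(nv), M = nv + seq_len(nm), P = nv + nm + seq_len(np))
}

module_sizes <- function(layout) {
  c(V = layout$n_visual, M = layout$n_memory, P = layout$n_perceiving)
}

module_grid <- function(layout, module) {
  switch(module, V = layout$visual_grid, M = layout$memory_grid,
         P = layout$perceiving_grid,
         stop("unknown module: ", module, call. = FALSE))
}

#' @export
print.module_layout <- function(x, ...) {
  cat(sprintf("Three-module layout: V=%d (%s), M=%d (%s), P=%d (%s), N=%d\n",
              x$n_visual, paste(x$visual_grid, collapse = "x"),
              x$n_memory, paste(x$memory_grid, collapse = "x"),
              x$n_perceiving, paste(x$perceiving_grid, collapse = "x"),
              layout_total(x)))
  invisible(x)
}
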