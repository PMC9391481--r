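#' Lesion configuration
#'
#' Describes a pathological state of the network: how many neurons die in
#' each module (necrosis) and how many incoming synaptic connections
#' survive per living target neuron (fan-in pruning). Only incoming
#' connectivity is pruned; fan-out pruning is out of scope.
#'
#' Fan-in budgets come in two forms. A per-projection budget
#' (`fan_in = list("P<-V" = 450)`) fixes the surviving fan-in from one
#' source module. A pooled budget
#' (`pooled = list(list(target = "P", sources = c("V", "M"), r = 1050))`)
#' constrains only the total over several source modules: each target
#' neuron keeps `r` survivors drawn uniformly from the pooled candidate
#' set, so the per-source split fluctuates around the source sizes. The
#' pooled form is how "impairment of bottom-up information" is expressed:
#' `r^(P<-V) + r^(P<-M) = 1050` of the 2100 connections into each
#' perceiving neuron.
#'
#' @param dead Named integer vector, e.g. `c(V = 90, M = 0, P = 0)`: number
#'   of neurons killed per module (missing modules default to 0).
#' @param fan_in Named list of per-projection surviving fan-in counts; names
#'   are `"target<-source"` with modules in `V`, `M`, `P`.
#' @param pooled List of pooled-budget specs, each a list with `target`
#'   (one module), `sources` (several modules) and `r` (total survivors).
#' @param seed RNG seed for the necrosis and pruning draws.
#' @return A `lesion_config`.
#' @seealso [make_lesion()]
#' @export
lesion_config <- function(dead = c(V = 0, M = 0, P = 0), fan_in = list(),
                          pooled = list(), seed = 1) {
  full <- c(V = 0L, M = 0L, P = 0L)
  if (length(dead)) {
    if (is.null(names(dead)) || !all(names(dead) %in% names(full)))
      stop("configuration error: `dead` must be named with modules V, M, P",
           call. = FALSE)
    full[names(dead)] <- as.integer(dead)
  }
  if (any(full < 0))
    stop("configuration error: negative dead counts", call. = FALSE)
  for (nm in names(fan_in))
    if (!grepl("^[VMP]<-[VMP]$", nm))
      stop("configuration error: fan_in name must look like \"P<-V\", got ", nm,
           call. = FALSE)
  for (pg in pooled) {
    if (!is.list(pg) || !all(c("target", "sources", "r") %in% names(pg)))
      stop("configuration error: pooled entries need target, sources, r",
           call. = FALSE)
    if (!pg$target %in% names(full) || !all(pg$sources %in% names(full)))
      stop("configuration error: pooled modules must be V, M or P",
           call. = FALSE)
  }
  structure(list(dead = full, fan_in = fan_in, pooled = pooled,
                 seed = as.integer(seed)),
            class = "lesion_config")
}

#' Realize a lesion as a binary connectivity mask
#'
#' Builds the `N x N` mask `eps` (1 = functional connection, 0 = absent)
#' from a [lesion_config()]. Dead neurons are chosen uniformly at random
#' within each module and encoded by zeroing their entire row and column
#' ("no input can be received and no outcome is given"); every living
#' target neuron of a constrained projection keeps exactly the budgeted
#' number of incoming connections, chosen uniformly without replacement
#' from the living sources. The draw is deterministic for a fixed config
#' seed.
#'
#' Dead neurons' states are clamped to -1 (non-active) by the dynamics and
#' excluded from overlap normalization: with zero fan-in the sign update
#' would otherwise just report the sign of the threshold, which is
#' meaningless for a dead cell.
#'
#' @param cfg A [lesion_config()].
#' @param layout A [module_layout()].
#' @return A `connectivity_mask`: list with the dense binary matrix `eps`,
#'   the sorted `dead` index vector, the generating `config`, the `layout`
#'   and the seed.
#' @export
make_lesion <- function(cfg, layout) {
  stopifnot(inherits(cfg, "lesion_config"), inherits(layout, "module_layout"))
  N <- layout_total(layout)
  rng <- module_ranges(layout)
  sizes <- module_sizes(layout)
  for (m in names(sizes))
    if (cfg$dead[[m]] > sizes[[m]])
      stop(sprintf("configuration error: cannot kill %d of %d neurons in module %s",
                   cfg$dead[[m]], sizes[[m]], m), call. = FALSE)
  mask <- local_seed(cfg$seed, {
    eps <- matrix(1, N, N)
    dead <- integer(0)
    for (m in names(sizes))
      if (cfg$dead[[m]] > 0)
        dead <- c(dead, sample(rng[[m]], cfg$dead[[m]]))
    dead <- sort(dead)
    if (length(dead)) {
      eps[dead, ] <- 0
      eps[, dead] <- 0
    }
    prune <- function(eps, targets, candidates, r) {
      r <- as.integer(r)
      if (r > length(candidates))
        stop(sprintf("configuration error: fan-in budget %d exceeds the %d living source neurons",
                     r, length(candidates)), call. = FALSE)
      for (i in targets) {
        row <- eps[i, ]
        row[candidates] <- 0
        row[sample(candidates, r)] <- 1
        eps[i, ] <- row
      }
      eps
    }
    for (nm in names(cfg$fan_in)) {
      target <- substr(nm, 1, 1); source <- substr(nm, 4, 4)
      eps <- prune(eps, setdiff(rng[[target]], dead),
                   setdiff(rng[[source]], dead), cfg$fan_in[[nm]])
    }
    for (pg in cfg$pooled)
      eps <- prune(eps, setdiff(rng[[pg$target]], dead),
                   setdiff(unlist(rng[pg$sources], use.names = FALSE), dead),
                   pg$r)
    list(eps = eps, dead = dead)
  })
  structure(list(eps = mask$eps, dead = mask$dead, config = cfg,
                 layout = layout, seed = cfg$seed),
            class = "connectivity_mask")
}

#' @export
print.connectivity_mask <- function(x, ...) {
  cat(sprintf("Connectivity mask: %d x %d, %d dead neurons, %d of %d connections absent\n",
              nrow(x$eps), ncol(x$eps), length(x$dead),
              length(x$eps) - sum(x$eps), length(x$eps)))
  invisible(x)
}

#' Sinusoidal per-module threshold schedules
#'
#' A slowly oscillating, module-wide firing threshold stands in for
#' impaired neuromodulator (acetylcholine) release: all neurons of module
#' `kappa` share `theta^kappa(t) = A * sin(2 * pi * (t + phase) / period)`.
#' The canonical perceiving-module impairment is `A = 0.02`, `period = 100`
#' steps. Modules without a schedule have threshold 0.
#'
#' @param V,M,P Optional numeric vectors `c(A = , period = , phase = )`
#'   (phase defaults to 0) giving the amplitude, period in steps, and phase
#'   offset in steps for each module.
#' @return A `threshold_schedule`.
#' @examples
#' threshold_schedule(P = c(A = 0.02, period = 100))
#' @export
threshold_schedule <- function(V = NULL, M = NULL, P = NULL) {
  parse1 <- function(x, m) {
    if (is.null(x)) return(NULL)
    x <- as.list(x)
    if (is.null(x$A) || is.null(x$period))
      stop("configuration error: schedule for ", m, " needs A and period",
           call. = FALSE)
    if (x$period < 1)
      stop("configuration error: schedule period must be >= 1", call. = FALSE)
    list(A = as.numeric(x$A), period = as.numeric(x$period),
         phase = as.numeric(x$phase %||% 0))
  }
  structure(list(V = parse1(V, "V"), M = parse1(M, "M"), P = parse1(P, "P")),
            class = "threshold_schedule")
}

#' Evaluate a threshold schedule at one time step
#'
#' @param sched A [threshold_schedule()] (or `NULL` for all-zero thresholds).
#' @param t Step index (the update from `s(t)` to `s(t+1)` uses `theta(t)`).
#' @param layout A [module_layout()].
#' @return Numeric threshold vector of length `N`.
#' @export
threshold_at <- function(sched, t, layout) {
  theta <- numeric(layout_total(layout))
  if (is.null(sched)) return(theta)
  stopifnot(inherits(sched, "threshold_schedule"), t >= 0)
  rng <- module_ranges(layout)
  for (m in c("V", "M", "P")) {
    sc <- sched[[m]]
    if (!is.null(sc))
      theta[rng[[m]]] <- sc$A * sin(2 * pi * (t + sc$phase) / sc$period)
  }
  theta
}

# Per-module scalar thresholds at (possibly several) phase-shifted times.
# Returns a 3 x length(t) matrix rows V, M, P; used by the batch engine.
schedule_scalars <- function(sched, t) {
  out <- matrix(0, 3, length(t), dimnames = list(c("V", "M", "P"), NULL))
  if (is.null(sched)) return(out)
  for (m in rownames(out)) {
    sc <- sched[[m]]
    if (!is.null(sc))
      out[m, ] <- sc$A * sin(2 * pi * (t + sc$phase) / sc$period)
  }
  out
}
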