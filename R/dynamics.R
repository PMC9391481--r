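#' External input signal to the visual module
#'
#' Input enters the network only through the visual module. Two modes are
#' supported: `"initialization"` (the default experimental protocol), where
#' the probe pattern is written into the visual block of the initial state
#' and no bias term is applied afterwards; and `"persistent"`, where
#' `strength * q` is added to the visual neurons' local fields for the
#' first `duration` update steps.
#'
#' @param q Numeric vector of length `n_visual` (the bias pattern).
#' @param mode `"initialization"` or `"persistent"`.
#' @param strength Scalar multiplier for the bias (persistent mode).
#' @param duration Number of steps the bias is applied (persistent mode).
#' @return An `input_signal`.
#' @export
input_signal <- function(q, mode = c("initialization", "persistent"),
                         strength = 1, duration = Inf) {
  mode <- match.arg(mode)
  structure(list(q = as.numeric(q), mode = mode,
                 strength = as.numeric(strength), duration = duration),
            class = "input_signal")
}

#' One synchronous update of the network state
#'
#' Applies the three-module update rule: every living neuron `i` of module
#' `kappa` computes its masked local field
#' `h_i = sum_j eps_ij w_ij s_j(t) + q_i [kappa = V] - theta_i` and takes
#' the new state `sgn(h_i)`, with the convention `sgn(u) = +1` for
#' `u >= 0` and `-1` otherwise. All neurons update simultaneously; dead
#' neurons stay clamped at -1.
#'
#' @param s State vector of length `N` with entries +-1.
#' @param w A `weight_matrix` (or a bare `N x N` matrix).
#' @param mask Optional `connectivity_mask`; `NULL` means full connectivity.
#' @param theta Threshold vector of length `N`, or a scalar (default 0).
#' @param q Optional bias vector of length `N` already padded with zeros
#'   outside the visual module (or `NULL`).
#' @return The updated +-1 state vector.
#' @export
update_state <- function(s, w, mask = NULL, theta = 0, q = NULL) {
  W <- if (inherits(w, "weight_matrix")) w$w else w
  if (length(s) != nrow(W))
    stop("consistency error: state length ", length(s),
         " does not match weight matrix dimension ", nrow(W), call. = FALSE)
  if (!all(s %in% c(-1, 1)))
    stop("consistency error: state entries must be +-1", call. = FALSE)
  if (!is.null(mask)) {
    if (!identical(dim(mask$eps), dim(W)))
      stop("consistency error: mask and weight dimensions differ", call. = FALSE)
    W <- W * mask$eps
  }
  h <- drop(W %*% s)
  if (!is.null(q)) h <- h + q
  h <- h - theta
  out <- as.numeric(2 * (h >= 0) - 1)
  if (!is.null(mask) && length(mask$dead)) out[mask$dead] <- -1
  out
}

#' Run the synchronous dynamics for a fixed number of steps
#'
#' Iterates [update_state()] from an initial state, recording every visited
#' state, and detects exact cycles in the recorded trajectory (binary
#' states make tolerance-free repetition detection correct). Convergence
#' onto an embedded attractor shows up as a detected period equal to the
#' embedding period `L`.
#'
#' @param initial Initial +-1 state vector (its visual block is overwritten
#'   with `input$q` when the input mode is `"initialization"`).
#' @param steps Number of updates (`>= 1`).
#' @param w A `weight_matrix`.
#' @param mask Optional `connectivity_mask`.
#' @param schedule Optional [threshold_schedule()]; the update from `s(t)`
#'   to `s(t+1)` uses `theta(t)`, with `t = 0` at the initial state.
#' @param input Optional [input_signal()].
#' @return A `trajectory`: list with `states` (`N x (steps+1)` matrix,
#'   column `t+1` holding `s(t)`), `detected_period`, `convergence_step`
#'   (onset of the detected cycle, `NA` if none), and the schedules used.
#' @export
run_simulation <- function(initial, steps, w, mask = NULL, schedule = NULL,
                           input = NULL) {
  stopifnot(inherits(w, "weight_matrix"), steps >= 1)
  layout <- w$layout
  N <- layout_total(layout)
  if (length(initial) != N)
    stop("consistency error: initial state has wrong length", call. = FALSE)
  W <- if (is.null(mask)) w$w else w$w * mask$eps
  dead <- if (is.null(mask)) integer(0) else mask$dead
  s <- as.numeric(initial)
  qpad <- NULL
  if (!is.null(input)) {
    rngV <- module_ranges(layout)$V
    if (length(input$q) != length(rngV))
      stop("consistency error: input q must have length n_visual", call. = FALSE)
    if (input$mode == "initialization") {
      s[rngV] <- input$q
    } else {
      qpad <- numeric(N)
      qpad[rngV] <- input$strength * input$q
    }
  }
  if (length(dead)) s[dead] <- -1
  states <- matrix(0, N, steps + 1L)
  states[, 1L] <- s
  for (t in seq_len(steps) - 1L) {
    h <- drop(W %*% s)
    if (!is.null(qpad) && t < input$duration) h <- h + qpad
    if (!is.null(schedule)) h <- h - threshold_at(schedule, t, layout)
    s <- as.numeric(2 * (h >= 0) - 1)
    if (length(dead)) s[dead] <- -1
    states[, t + 2L] <- s
  }
  traj <- structure(list(states = states, layout = layout, mask = mask,
                         schedule = schedule, input = input,
                         detected_period = NA_integer_,
                         convergence_step = NA_integer_),
                    class = "trajectory")
  cyc <- detect_cycle(traj, max_period = steps)
  if (!is.null(cyc)) {
    traj$detected_period <- cyc$period
    traj$convergence_step <- cyc$onset
  }
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d steps, N=%d%s\n", ncol(x$states) - 1L,
              nrow(x$states),
              if (is.na(x$detected_period)) ", no cycle detected"
              else sprintf(", period %d from step %d",
                           x$detected_period, x$convergence_step)))
  invisible(x)
}

#' Detect the smallest exact cycle in a trajectory
#'
#' Scans for the smallest period `p <= max_period` and the earliest onset
#' such that `s(t) = s(t + p)` exactly for every recorded `t >= onset`.
#'
#' @param traj A `trajectory`.
#' @param max_period Largest period to consider.
#' @return `list(period, onset)` or `NULL` when no cycle is present.
#' @export
detect_cycle <- function(traj, max_period) {
  keys <- apply(traj$states, 2L, paste, collapse = "")
  n <- length(keys)                       # states s(0) .. s(n-1)
  for (p in seq_len(min(max_period, n - 1L))) {
    eq <- keys[seq_len(n - p)] == keys[p + seq_len(n - p)]
    if (eq[n - p]) {                      # cycle must persist to the end
      bad <- which(!eq)
      onset <- if (length(bad)) max(bad) else 0L
      return(list(period = p, onset = as.integer(onset)))
    }
  }
  NULL
}

#' Overlap order parameters with the embedded patterns
#'
#' For one module, the overlap of a state with embedded pattern
#' `(mu, lambda)` is `m = (1 / n_living) * sum_i s_i xi_i^{mu,lambda}`,
#' summing over the module's living neurons. It equals 1 exactly when the
#' state matches the pattern on every living neuron and -1 on the
#' anti-pattern; two independent random +-1 vectors have overlap
#' `O(1/sqrt(n))`.
#'
#' @param s State vector of length `N`.
#' @param ps A `pattern_set`.
#' @param module `"V"`, `"M"` or `"P"`.
#' @param mask Optional `connectivity_mask` whose dead neurons are excluded
#'   from the sum and the normalization.
#' @return Numeric vector of `K * L` overlaps in `[-1, 1]`, ordered by
#'   [pattern_index()].
#' @export
overlap <- function(s, ps, module = c("V", "M", "P"), mask = NULL) {
  module <- match.arg(module)
  idx <- module_ranges(ps$layout)[[module]]
  if (!is.null(mask)) idx <- setdiff(idx, mask$dead)
  if (!length(idx))
    stop("undefined-overlap error: module ", module, " has no living neurons",
         call. = FALSE)
  drop(crossprod(ps$xi[idx, , drop = FALSE], s[idx])) / length(idx)
}

#' Noisy recall probe
#'
#' Builds the probe state for recall experiments from the embedded state
#' `(mu, lambda)`: a fraction of its visual bits is flipped
#' (`round(flip_frac * n_visual)` distinct positions chosen uniformly),
#' optionally a fraction of memory bits too.
#'
#' With `perceiving = "pattern"` the perceiving block starts on the
#' pattern: the probe is a point in the attractor's basin, the right
#' construction for basin-size questions. With `perceiving = "random"` the
#' perceiving block is i.i.d. random: the network has to *form* the
#' percept from the bottom up, the construction the scenario runners use —
#' starting the perceiving module on the answer would make initial
#' erroneous perception impossible by fiat.
#'
#' @param ps A `pattern_set`.
#' @param mu Probed cycle.
#' @param lambda Phase of the probed state (default 1).
#' @param flip_frac Fraction of visual bits to flip.
#' @param seed RNG seed for the flip positions (and the random perceiving
#'   block).
#' @param perceiving `"pattern"` or `"random"` (see Details).
#' @param memory_flip Fraction of memory bits to flip (default 0).
#' @return A +-1 state vector of length `N`.
#' @export
noisy_probe <- function(ps, mu, lambda = 1, flip_frac = 0.05, seed = 1,
                        perceiving = c("pattern", "random"),
                        memory_flip = 0) {
  perceiving <- match.arg(perceiving)
  stopifnot(mu >= 1, mu <= ps$K, lambda >= 1, lambda <= ps$L,
            flip_frac >= 0, flip_frac <= 1, memory_flip >= 0,
            memory_flip <= 1)
  s <- ps$xi[, pattern_index(mu, lambda, ps$L)]
  rng <- module_ranges(ps$layout)
  local_seed(seed, {
    nflip <- round(flip_frac * length(rng$V))
    if (nflip > 0) {
      flip <- sample(rng$V, nflip)
      s[flip] <- -s[flip]
    }
    mflip <- round(memory_flip * length(rng$M))
    if (mflip > 0) {
      flip <- sample(rng$M, mflip)
      s[flip] <- -s[flip]
    }
    if (perceiving == "random")
      s[rng$P] <- sample(c(-1, 1), length(rng$P), replace = TRUE)
  })
  s
}
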