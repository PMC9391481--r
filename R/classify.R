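# Outcome classification and the batched simulation engine behind the
# scenario runners. The runners only ever need the per-step best-matching
# perceiving pattern, so the engine tracks that series instead of storing
# whole trajectories, and runs all probes of a lesion configuration as
# columns of one matrix product per step.

OUTCOME_LABELS <- c("veridical", "transient-error-then-veridical",
                    "hallucination-like", "non-convergent")

#' Classify a recall trajectory
#'
#' At every recorded step the perceiving module's state is compared (by
#' overlap on living perceiving neurons) against the `K` embedded
#' perceiving patterns; a step "matches" cycle `mu'` when that overlap
#' reaches `match_threshold`. The trajectory is then labelled:
#'
#' * `veridical` — the final `sustain` steps all match the probed cycle
#'   `mu`, and no earlier window of `sustain` consecutive steps failed to
#'   match `mu`;
#' * `transient-error-then-veridical` — veridical at the end, but some
#'   earlier `sustain` consecutive steps did not match `mu` (sustained
#'   erroneous perception that self-corrected);
#' * `hallucination-like` — some window of `sustain` consecutive steps
#'   (possibly at the end) matches one other cycle `mu' != mu`, without a
#'   veridical ending;
#' * `non-convergent` — none of the above.
#'
#' Every trajectory receives exactly one label, tested in this order.
#'
#' @param traj A `trajectory` from [run_simulation()].
#' @param ps The `pattern_set` embedded in the network.
#' @param input_cycle The probed cycle `mu`.
#' @param match_threshold Overlap level counting as a match (default 0.95,
#'   so exact-orbit entry always matches and single-bit excursions do not
#'   flip labels).
#' @param sustain Number of consecutive steps a match must persist
#'   (default `L`, one full cycle period).
#' @return An `outcome_report`: list with `label`, `input_cycle`,
#'   `final_cycle` (`NA` when the end is unmatched),
#'   `perceiving_match_series` (data frame `t`, `best_cycle`, `overlap`)
#'   and `convergence_step`.
#' @export
classify_outcome <- function(traj, ps, input_cycle,
                             match_threshold = 0.95, sustain = ps$L) {
  stopifnot(inherits(traj, "trajectory"), inherits(ps, "pattern_set"))
  nstep <- ncol(traj$states)
  if (nstep < sustain)
    stop("trajectory too short: needs at least `sustain` recorded steps",
         call. = FALSE)
  mask <- traj$mask
  idxP <- module_ranges(ps$layout)$P
  if (!is.null(mask)) idxP <- setdiff(idxP, mask$dead)
  Pmat <- ps$xi[idxP, pattern_index(seq_len(ps$K), 1L, ps$L), drop = FALSE]
  m <- crossprod(Pmat, traj$states[idxP, , drop = FALSE]) / length(idxP)
  best <- apply(m, 2L, which.max)
  bestval <- m[cbind(best, seq_len(nstep))]
  lab <- label_outcome(best, bestval, input_cycle, match_threshold, sustain)
  structure(list(label = lab$label, input_cycle = as.integer(input_cycle),
                 final_cycle = lab$final_cycle,
                 perceiving_match_series =
                   data.frame(t = seq_len(nstep) - 1L, best_cycle = best,
                              overlap = bestval),
                 convergence_step = traj$convergence_step),
            class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("Outcome: %s (probe cycle %d -> final %s)\n", x$label,
              x$input_cycle,
              if (is.na(x$final_cycle)) "none" else x$final_cycle))
  invisible(x)
}

# Shared labelling rule. best/bestval are the per-step best perceiving
# cycle index and its overlap; matched(t) is that index where the overlap
# clears the threshold, NA otherwise.
label_outcome <- function(best, bestval, mu, threshold, sustain) {
  n <- length(best)
  matched <- ifelse(bestval >= threshold, best, NA_integer_)
  tail_idx <- (n - sustain + 1L):n
  end_veridical <- all(!is.na(matched[tail_idx]) & matched[tail_idx] == mu)
  # sustained failure to match the probed cycle (NA counts as mismatch)
  mis <- is.na(matched) | matched != mu
  r <- rle(mis)
  had_error <- any(r$values & r$lengths >= sustain)
  final_cycle <- if (all(!is.na(matched[tail_idx])) &&
                     length(unique(matched[tail_idx])) == 1L)
    matched[n] else NA_integer_
  if (end_veridical) {
    label <- if (had_error) "transient-error-then-veridical" else "veridical"
  } else {
    codes <- ifelse(is.na(matched), -1L, matched)
    rc <- rle(codes)
    hall <- any(rc$values > 0L & rc$values != mu & rc$lengths >= sustain)
    label <- if (hall) "hallucination-like" else "non-convergent"
  }
  list(label = label, final_cycle = final_cycle)
}

# Batched probe runner. S0: N x C matrix of initial states (columns =
# probes). Returns per-column best-cycle index and overlap series
# ((steps+1) x C matrices). `phases` gives a per-column time offset for
# the threshold schedule. When no schedule is present the run stops early
# once every column exactly repeats its state L steps earlier; the
# remaining series entries are then filled by cyclic continuation, which
# is exact for the deterministic update.
run_probe_batch <- function(W, S0, steps, ps, dead = integer(0),
                            schedule = NULL, phases = NULL) {
  layout <- ps$layout
  rng <- module_ranges(layout)
  idxP <- setdiff(rng$P, dead)
  Pmat <- ps$xi[idxP, pattern_index(seq_len(ps$K), 1L, ps$L), drop = FALSE]
  C <- ncol(S0)
  L <- ps$L
  if (length(dead)) S0[dead, ] <- -1
  record <- function(S) {
    m <- crossprod(Pmat, S[idxP, , drop = FALSE]) / length(idxP)
    b <- max.col(t(m), ties.method = "first")
    list(best = b, val = m[cbind(b, seq_len(C))])
  }
  best <- matrix(NA_integer_, steps + 1L, C)
  val <- matrix(NA_real_, steps + 1L, C)
  r0 <- record(S0)
  best[1L, ] <- r0$best; val[1L, ] <- r0$val
  ring <- vector("list", L)            # states L steps back, for early stop
  ring[[1L]] <- S0
  S <- S0
  early <- is.null(schedule)
  for (t in seq_len(steps) - 1L) {
    H <- W %*% S
    if (!is.null(schedule)) {
      th <- schedule_scalars(schedule, (t + (phases %||% 0)))
      for (m in c("V", "M", "P"))
        if (any(th[m, ] != 0))
          H[rng[[m]], ] <- sweep(H[rng[[m]], , drop = FALSE], 2L, th[m, ], "-")
    }
    S <- 2 * (H >= 0) - 1
    if (length(dead)) S[dead, ] <- -1
    r <- record(S)
    best[t + 2L, ] <- r$best; val[t + 2L, ] <- r$val
    if (early && t + 1L >= L) {
      slot <- (t + 1L) %% L + 1L
      if (isTRUE(all(S == ring[[slot]]))) {
        # all columns repeat with period dividing L: continue cyclically
        if (t + 1L < steps)
          for (tt in (t + 3L):(steps + 1L)) {
            best[tt, ] <- best[tt - L, ]; val[tt, ] <- val[tt - L, ]
          }
        break
      }
    }
    ring[[(t + 1L) %% L + 1L]] <- S
  }
  list(best = best, val = val)
}
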