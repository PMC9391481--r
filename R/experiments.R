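#' Scenario runners for destabilization experiments
#'
#' The three runners share one protocol: build a lesioned network, probe it
#' with noisy visual input on each embedded cycle, run the synchronous
#' dynamics, and classify every run with [classify_outcome()]. They differ
#' in which pathological axis is swept:
#'
#' * [run_bottom_up_impairment()] — prunes the pooled bottom-up fan-in of
#'   every perceiving neuron (survivors drawn from the 2100 V and M
#'   sources; the canonical impaired budget is 1050), over repeated random
#'   mask configurations.
#' * [run_threshold_fluctuation()] — applies a slow sinusoidal
#'   perceiving-module threshold (canonically `0.02 * sin(2*pi*t/100)`) and
#'   varies the probe onset phase across one full modulation period.
#' * [run_combined_necrosis()] — sweeps a grid of combined lesions (cell
#'   death plus pruning on several projections), repeating each cell over
#'   random configurations and flagging "typical cases" where one outcome
#'   label dominates.
#'
#' @param ps A `pattern_set`.
#' @param w The matching `weight_matrix`.
#' @param budget Pooled surviving fan-in per perceiving neuron from V and M
#'   jointly (full connectivity is `n_visual + n_memory`).
#' @param n_config Number of independent random mask configurations.
#' @param n_probe Probes per configuration; probe `j` targets cycle
#'   `((j - 1) mod K) + 1`.
#' @param steps Updates per run (default `10 * L`).
#' @param flip_frac Fraction of visual bits flipped in each probe.
#' @param match_threshold,sustain Passed to the outcome classifier.
#' @param seed Master seed; all lesion and noise seeds derive from it, and
#'   the returned object carries the full seed manifest.
#' @return A `sweep_result`: list with `outcomes` (one row per run:
#'   configuration, probe, probed cycle, label, final cycle), `frequencies`
#'   (proportion of each label, summing to 1), the run parameters and the
#'   seed manifest.
#' @name experiments
NULL

#' @rdname experiments
#' @export
run_bottom_up_impairment <- function(ps, w, budget, n_config = 20,
                                     n_probe = ps$K, steps = 10 * ps$L,
                                     flip_frac = 0.05, match_threshold = 0.95,
                                     sustain = ps$L, seed = 1) {
  stopifnot(inherits(ps, "pattern_set"), inherits(w, "weight_matrix"))
  pool <- ps$layout$n_visual + ps$layout$n_memory
  if (budget < 0 || budget > pool)
    stop(sprintf("infeasible budget: %d survivors from a pool of %d", budget,
                 pool), call. = FALSE)
  seeds <- derive_seeds(seed, n_config * (1L + n_probe))
  manifest <- matrix(seeds, n_config, 1L + n_probe, byrow = TRUE)
  rows <- vector("list", n_config)
  for (cf in seq_len(n_config)) {
    cfg <- lesion_config(pooled = list(list(target = "P",
                                            sources = c("V", "M"),
                                            r = budget)),
                         seed = manifest[cf, 1L])
    mask <- make_lesion(cfg, ps$layout)
    rows[[cf]] <- probe_and_classify(ps, w, mask, NULL, NULL,
                                     n_probe, steps, flip_frac,
                                     match_threshold, sustain,
                                     manifest[cf, -1L], config = cf)
  }
  new_sweep_result(do.call(rbind, rows),
                   params = list(experiment = "bottom_up_impairment",
                                 budget = budget, n_config = n_config,
                                 n_probe = n_probe, steps = steps,
                                 flip_frac = flip_frac,
                                 match_threshold = match_threshold,
                                 sustain = sustain),
                   seed = seed, seed_manifest = manifest)
}

#' @rdname experiments
#' @param sched A [threshold_schedule()] (the perceiving-module entry is
#'   the one under study).
#' @param phases Integer probe onset phases (time offsets into the
#'   modulation); default `0:(period - 1)`, one probe per phase.
#' @param lesion Optional [lesion_config()] applied before probing. At
#'   full connectivity the pseudo-inverse construction makes every
#'   on-attractor local field exactly +-1, so a small threshold is inert;
#'   the schedule only bites once pruning has shrunk the fields.
#' @export
run_threshold_fluctuation <- function(ps, w, sched, phases = NULL,
                                      n_probe = 1, lesion = NULL,
                                      steps = NULL, flip_frac = 0.05,
                                      match_threshold = 0.95,
                                      sustain = ps$L, seed = 1) {
  stopifnot(inherits(ps, "pattern_set"), inherits(w, "weight_matrix"),
            inherits(sched, "threshold_schedule"))
  period <- sched$P$period %||% sched$V$period %||% sched$M$period %||% ps$L
  if (is.null(phases)) phases <- 0:(period - 1)
  if (is.null(steps)) steps <- max(10L * ps$L, as.integer(period))
  mask <- if (is.null(lesion)) NULL else make_lesion(lesion, ps$layout)
  W <- if (is.null(mask)) w$w else w$w * mask$eps
  dead <- if (is.null(mask)) integer(0) else mask$dead
  noise_seeds <- derive_seeds(seed, n_probe)
  rows <- vector("list", n_probe)
  for (pr in seq_len(n_probe)) {
    mu <- (pr - 1L) %% ps$K + 1L
    s0 <- noisy_probe(ps, mu, 1L, flip_frac, noise_seeds[pr],
                      perceiving = "random")
    S0 <- matrix(s0, length(s0), length(phases))  # same probe, all phases
    res <- run_probe_batch(W, S0, steps, ps, dead, sched, phases)
    lab <- lapply(seq_along(phases), function(j)
      label_outcome(res$best[, j], res$val[, j], mu, match_threshold, sustain))
    rows[[pr]] <- data.frame(config = 1L, probe = pr, mu = mu,
                             phase = phases,
                             label = vapply(lab, `[[`, "", "label"),
                             final_cycle = vapply(lab, function(l)
                               as.integer(l$final_cycle), 1L))
  }
  new_sweep_result(do.call(rbind, rows),
                   params = list(experiment = "threshold_fluctuation",
                                 schedule = sched, phases = phases,
                                 lesion = lesion, n_probe = n_probe,
                                 steps = steps, flip_frac = flip_frac,
                                 match_threshold = match_threshold,
                                 sustain = sustain),
                   seed = seed, seed_manifest = noise_seeds)
}

#' @rdname experiments
#' @param cells Named list of [lesion_config()] objects, one per grid cell;
#'   each cell's lesion is re-drawn `n_config` times with derived seeds.
#' @param typical_threshold A cell is flagged "typical" for a label when
#'   that label's frequency over its runs reaches this fraction.
#' @export
run_combined_necrosis <- function(ps, w, cells, n_config = 10,
                                  n_probe = ps$K, steps = 10 * ps$L,
                                  flip_frac = 0.05, match_threshold = 0.95,
                                  sustain = ps$L, typical_threshold = 0.5,
                                  seed = 1) {
  stopifnot(inherits(ps, "pattern_set"), inherits(w, "weight_matrix"),
            is.list(cells), length(cells) >= 1)
  if (is.null(names(cells)))
    names(cells) <- paste0("cell", seq_along(cells))
  seeds <- derive_seeds(seed, length(cells) * n_config * (1L + n_probe))
  manifest <- array(seeds, c(length(cells), n_config, 1L + n_probe))
  rows <- list()
  for (ci in seq_along(cells)) {
    stopifnot(inherits(cells[[ci]], "lesion_config"))
    for (cf in seq_len(n_config)) {
      cfg <- cells[[ci]]
      cfg$seed <- manifest[ci, cf, 1L]
      mask <- make_lesion(cfg, ps$layout)
      r <- probe_and_classify(ps, w, mask, NULL, NULL, n_probe, steps,
                              flip_frac, match_threshold, sustain,
                              manifest[ci, cf, -1L], config = cf)
      r$cell <- names(cells)[ci]
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  per_cell <- lapply(split(out$label, out$cell), function(l)
    prop.table(table(factor(l, levels = OUTCOME_LABELS))))
  typical <- lapply(per_cell, function(f)
    names(f)[f >= typical_threshold])
  new_sweep_result(out,
                   params = list(experiment = "combined_necrosis",
                                 cells = cells, n_config = n_config,
                                 n_probe = n_probe, steps = steps,
                                 flip_frac = flip_frac,
                                 match_threshold = match_threshold,
                                 sustain = sustain,
                                 typical_threshold = typical_threshold),
                   seed = seed, seed_manifest = manifest,
                   extra = list(cell_frequencies = per_cell,
                                typical_labels = typical))
}

# One lesion configuration, n_probe noisy probes run as a batch.
probe_and_classify <- function(ps, w, mask, schedule, phases, n_probe, steps,
                               flip_frac, match_threshold, sustain,
                               noise_seeds, config) {
  W <- if (is.null(mask)) w$w else w$w * mask$eps
  dead <- if (is.null(mask)) integer(0) else mask$dead
  mu_vec <- (seq_len(n_probe) - 1L) %% ps$K + 1L
  S0 <- vapply(seq_len(n_probe), function(j)
    noisy_probe(ps, mu_vec[j], 1L, flip_frac, noise_seeds[j],
                perceiving = "random"),
    numeric(layout_total(ps$layout)))
  res <- run_probe_batch(W, S0, steps, ps, dead, schedule, phases)
  lab <- lapply(seq_len(n_probe), function(j)
    label_outcome(res$best[, j], res$val[, j], mu_vec[j],
                  match_threshold, sustain))
  data.frame(config = config, probe = seq_len(n_probe), mu = mu_vec,
             label = vapply(lab, `[[`, "", "label"),
             final_cycle = vapply(lab, function(l) as.integer(l$final_cycle),
                                  1L))
}

new_sweep_result <- function(outcomes, params, seed, seed_manifest,
                             extra = list()) {
  freq <- prop.table(table(factor(outcomes$label, levels = OUTCOME_LABELS)))
  structure(c(list(outcomes = outcomes, frequencies = freq, params = params,
                   seed = seed, seed_manifest = seed_manifest), extra),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep (%s): %d runs\n", x$params$experiment, nrow(x$outcomes)))
  f <- x$frequencies
  for (nm in names(f))
    cat(sprintf("  %-31s %5.1f%%\n", nm, 100 * f[[nm]]))
  invisible(x)
}

#' Export sweep outcomes
#'
#' `write_sweep_csv()` writes one row per configuration and probe;
#' `write_sweep_summary()` writes the label frequencies, parameters and
#' seed manifest as JSON, so a sweep is fully reproducible from its
#' summary alone.
#'
#' @param sw A `sweep_result`.
#' @param path Output file path.
#' @export
write_sweep_csv <- function(sw, path) {
  stopifnot(inherits(sw, "sweep_result"))
  utils::write.csv(sw$outcomes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
write_sweep_summary <- function(sw, path) {
  stopifnot(inherits(sw, "sweep_result"))
  params <- sw$params
  params$schedule <- NULL; params$cells <- NULL; params$lesion <- NULL
  jsonlite::write_json(
    list(experiment = sw$params$experiment,
         frequencies = as.list(sw$frequencies), params = params,
         seed = sw$seed, seed_manifest = sw$seed_manifest,
         typical_labels = sw$typical_labels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
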