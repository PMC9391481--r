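#' Experiment configuration files
#'
#' Experiments are described by YAML (or JSON) files covering the network
#' layout, pattern-set size and seeds, the lesion, threshold schedules,
#' probe noise and run lengths. [load_config()] reads a file, fills in
#' defaults for every omitted field and validates the result;
#' [validate_config()] checks feasibility and names the offending field on
#' failure; [default_config()] returns the full default (the intact
#' 3000-neuron network, `K = 11` cycles of period `L = 10`, no lesion, no
#' schedules). An empty file therefore loads as the no-pathology control.
#'
#' Recognized top-level fields: `experiment` (`recall`,
#' `bottom_up_impairment`, `threshold_fluctuation`, `combined_necrosis`),
#' `layout` (`n_visual`, `n_memory`, `n_perceiving`), `K`, `L`, `seeds`
#' (`patterns`, `lesion`, `noise`), `lesion` (`dead`, `fan_in`, `pooled`),
#' `schedule` (per-module `A`, `period`, `phase`), `input`
#' (`mode`, `flip_frac`, `strength`, `duration`), `run` (`steps`,
#' `n_config`, `n_probe`, `phases`), `classify` (`match_threshold`,
#' `sustain`, `typical_threshold`), `output` (directory).
#'
#' @param path Path to a YAML or JSON config file.
#' @param cfg A config list as returned by [load_config()].
#' @return A validated `experiment_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("validation error: no such config file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()         # empty file -> all defaults
  if (!is.list(raw))
    stop("validation error: config root must be a mapping", call. = FALSE)
  cfg <- merge_config(default_config(), raw)
  validate_config(cfg)
}

#' @rdname load_config
#' @export
default_config <- function() {
  structure(list(
    experiment = "recall",
    layout = list(n_visual = 900, n_memory = 1200, n_perceiving = 900),
    K = 11, L = 10,
    seeds = list(patterns = 101, lesion = 202, noise = 303),
    lesion = NULL,
    schedule = NULL,
    input = list(mode = "initialization", flip_frac = 0.05,
                 strength = 1, duration = Inf),
    run = list(steps = 100, n_config = 20, n_probe = 11, phases = NULL),
    classify = list(match_threshold = 0.95, sustain = 10,
                    typical_threshold = 0.5),
    output = NULL
  ), class = "experiment_config")
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' @rdname load_config
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("validation error in `%s`: %s", field, msg), call. = FALSE)
  known <- c(names(default_config()),
             "lesion_config", "threshold_schedule", "layout_obj")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    fail(unknown[1], "unknown field")
  if (!cfg$experiment %in% c("recall", "bottom_up_impairment",
                             "threshold_fluctuation", "combined_necrosis"))
    fail("experiment", paste("unknown experiment type", cfg$experiment))
  lay <- tryCatch(do.call(module_layout, cfg$layout),
                  error = function(e) fail("layout", conditionMessage(e)))
  N <- layout_total(lay)
  if (cfg$K < 1 || cfg$L < 1) fail("K", "K and L must be >= 1")
  if (cfg$K * cfg$L > N / 4)
    fail("K", sprintf("K*L = %d exceeds the capacity bound N/4 = %.0f",
                      cfg$K * cfg$L, N / 4))
  for (s in c("patterns", "lesion", "noise"))
    if (is.null(cfg$seeds[[s]]) || !is.numeric(cfg$seeds[[s]]))
      fail(paste0("seeds.", s), "every stochastic component needs an explicit integer seed")
  if (!is.null(cfg$lesion)) {
    lc <- tryCatch(
      lesion_config(dead = unlist(cfg$lesion$dead %||% c(V = 0, M = 0, P = 0)),
                    fan_in = cfg$lesion$fan_in %||% list(),
                    pooled = cfg$lesion$pooled %||% list(),
                    seed = cfg$seeds$lesion),
      error = function(e) fail("lesion", conditionMessage(e)))
    sizes <- module_sizes(lay)
    for (nm in names(lc$fan_in)) {
      src <- substr(nm, 4, 4)
      avail <- sizes[[src]] - lc$dead[[src]]
      if (lc$fan_in[[nm]] > avail)
        fail(paste0("lesion.fan_in.", nm),
             sprintf("budget %d exceeds %d living source neurons",
                     lc$fan_in[[nm]], avail))
    }
    for (pg in lc$pooled) {
      avail <- sum(sizes[pg$sources] - lc$dead[pg$sources])
      if (pg$r > avail)
        fail("lesion.pooled",
             sprintf("pooled budget %d exceeds %d living source neurons",
                     pg$r, avail))
    }
    cfg$lesion_config <- lc
  }
  if (!is.null(cfg$schedule)) {
    sc <- tryCatch(do.call(threshold_schedule, cfg$schedule),
                   error = function(e) fail("schedule", conditionMessage(e)))
    cfg$threshold_schedule <- sc
  }
  if (cfg$input$flip_frac < 0 || cfg$input$flip_frac > 1)
    fail("input.flip_frac", "must be in [0, 1]")
  if (!cfg$input$mode %in% c("initialization", "persistent"))
    fail("input.mode", "must be initialization or persistent")
  if (cfg$run$steps < 1) fail("run.steps", "must be >= 1")
  cfg$layout_obj <- lay
  class(cfg) <- "experiment_config"
  invisible(cfg)
}
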