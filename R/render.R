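#' Render a network state as bit-pattern grids
#'
#' Writes one image per module (30x30, 30x40 and 30x30 grids at the default
#' layout) with active (+1) neurons dark and inactive (-1) neurons light.
#' In `"pbm"` mode the files are ASCII PBM bitmaps identical in format to
#' serialized patterns; in `"png"` mode dead neurons are additionally
#' marked in red.
#'
#' @param s State vector of length `N`.
#' @param layout A [module_layout()].
#' @param prefix Output path prefix; files are `<prefix>_V.<ext>` etc.
#' @param format `"pbm"` or `"png"`.
#' @param dead Optional dead-neuron indices (PNG mode only).
#' @return Named character vector of the written file paths, invisibly.
#' @export
render_state <- function(s, layout, prefix, format = c("pbm", "png"),
                         dead = integer(0)) {
  format <- match.arg(format)
  stopifnot(inherits(layout, "module_layout"))
  if (length(s) != layout_total(layout))
    stop("layout mismatch: state length ", length(s), " but layout has ",
         layout_total(layout), " neurons", call. = FALSE)
  rng <- module_ranges(layout)
  out <- character(0)
  for (m in c("V", "M", "P")) {
    grid <- module_grid(layout, m)
    block <- s[rng[[m]]]
    path <- paste0(prefix, "_", m, ".", format)
    if (format == "pbm") {
      write_pbm(block, grid, path)
    } else {
      # +1 -> dark (0), -1 -> light (1); dead neurons red
      g <- matrix(ifelse(block > 0, 0, 1), grid[1], grid[2], byrow = TRUE)
      img <- array(rep(g, 3L), dim = c(grid[1], grid[2], 3L))
      d <- match(intersect(dead, rng[[m]]), rng[[m]])
      if (length(d)) {
        rows <- (d - 1L) %/% grid[2] + 1L
        cols <- (d - 1L) %% grid[2] + 1L
        img[cbind(rows, cols, 1L)] <- 1
        img[cbind(rows, cols, 2L)] <- 0.2
        img[cbind(rows, cols, 3L)] <- 0.2
      }
      png::writePNG(img, path)
    }
    out[m] <- path
  }
  invisible(out)
}

#' Export a trajectory's overlap time series as CSV
#'
#' Long format with one row per step, module and embedded pattern:
#' columns `t`, `module`, `mu`, `lambda`, `m` (the overlap order
#' parameter).
#'
#' @param traj A `trajectory`.
#' @param ps The embedded `pattern_set`.
#' @param path Output CSV path.
#' @export
write_trajectory_csv <- function(traj, ps, path) {
  stopifnot(inherits(traj, "trajectory"), inherits(ps, "pattern_set"))
  nstep <- ncol(traj$states)
  KL <- ps$K * ps$L
  rows <- vector("list", 3L)
  names(rows) <- c("V", "M", "P")
  for (m in names(rows)) {
    ov <- vapply(seq_len(nstep), function(j)
      overlap(traj$states[, j], ps, m, traj$mask), numeric(KL))
    rows[[m]] <- data.frame(
      t = rep(seq_len(nstep) - 1L, each = KL), module = m,
      mu = rep(rep(seq_len(ps$K), each = ps$L), nstep),
      lambda = rep(rep(seq_len(ps$L), ps$K), nstep),
      m = as.vector(ov))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
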