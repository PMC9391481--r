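# ASCII PBM (P1) bitmap I/O. A +-1 state block maps to bits 1/0; the
# bitmap is filled row-major, matching the on-screen grid orientation.

write_pbm <- function(x, grid, path) {
  grid <- as.integer(grid)
  if (length(x) != prod(grid))
    stop(sprintf("format error: %d values cannot fill a %dx%d bitmap",
                 length(x), grid[1], grid[2]), call. = FALSE)
  bits <- ifelse(x > 0, "1", "0")
  rows <- vapply(seq_len(grid[1]), function(r)
    paste(bits[(r - 1L) * grid[2] + seq_len(grid[2])], collapse = " "),
    character(1))
  writeLines(c("P1", paste(grid[2], grid[1]), rows), path)
  invisible(path)
}

read_pbm <- function(path) {
  if (!file.exists(path))
    stop("format error: no such PBM file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]       # strip comment lines
  tok <- unlist(strsplit(paste(lines, collapse = " "), "\\s+"))
  tok <- tok[nzchar(tok)]
  if (length(tok) < 3L || tok[1] != "P1")
    stop("format error: not an ASCII PBM (P1) file: ", path, call. = FALSE)
  wd <- suppressWarnings(as.integer(tok[2]))
  ht <- suppressWarnings(as.integer(tok[3]))
  if (is.na(wd) || is.na(ht) || wd < 1L || ht < 1L)
    stop("format error: malformed PBM header in ", path, call. = FALSE)
  bits <- tok[-(1:3)]
  if (length(bits) != wd * ht || !all(bits %in% c("0", "1")))
    stop(sprintf("format error: %s declares %dx%d pixels but carries %d tokens",
                 path, ht, wd, length(bits)), call. = FALSE)
  v <- ifelse(bits == "1", 1, -1)
  attr(v, "grid") <- c(ht, wd)
  v
}
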