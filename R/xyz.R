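#' Read and write extended XYZ trajectory files
#'
#' Minimal extended-XYZ dialect: per frame an atom-count line, a comment
#' line of whitespace-separated `key=value` pairs (numeric values parsed as
#' numeric), then one `symbol x y z` line per atom.  `write_xyz` followed by
#' `read_xyz` reproduces the frames up to floating-point formatting
#' (1e-10).
#'
#' @param frames List of frames; each frame is a list with `symbols`
#'   (character), `coords` (n x 3 numeric matrix) and optional `info`
#'   (named list of scalar values).
#' @param path File path.
#' @return `read_xyz` returns the frame list (empty file gives an empty
#'   list); `write_xyz` returns `path` invisibly.
#' @export
write_xyz <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$coords)
    if (length(fr$symbols) != n)
      stop("frame has ", length(fr$symbols), " symbols for ", n, " atoms")
    writeLines(as.character(n), con)
    info <- fr$info
    comment <- if (length(info) > 0)
      paste(names(info), vapply(info, function(v)
        if (is.numeric(v)) sprintf("%.15g", v) else as.character(v), ""),
        sep = "=", collapse = " ")
    else ""
    writeLines(comment, con)
    writeLines(sprintf("%s %.15g %.15g %.15g", fr$symbols,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  frame_idx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_idx <- frame_idx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0)
      stop("malformed atom count at line ", i, " (frame ", frame_idx, ")")
    if (i + 1L + n > length(lines))
      stop("frame ", frame_idx, " declares ", n,
           " atoms but the file ends at line ", length(lines))
    info <- .parse_xyz_comment(lines[i + 1L])
    body <- lines[(i + 2L):(i + 1L + n)]
    if (n == 0L) body <- character(0)
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(toks, length, 0L) < 4L)
    if (length(bad) > 0)
      stop("malformed coordinate line ", i + 1L + bad[1], " in frame ",
           frame_idx)
    symbols <- vapply(toks, `[[`, "", 1L)
    coords <- matrix(0, n, 3)
    for (j in seq_len(n)) {
      xyz <- suppressWarnings(as.numeric(toks[[j]][2:4]))
      if (any(is.na(xyz)))
        stop("non-numeric coordinates at line ", i + 1L + j, " in frame ",
             frame_idx)
      coords[j, ] <- xyz
    }
    frames[[frame_idx]] <- list(symbols = symbols, coords = coords,
                                info = info)
    i <- i + 2L + n
  }
  frames
}

.parse_xyz_comment <- function(line) {
  line <- trimws(line)
  if (!nzchar(line)) return(list())
  pairs <- strsplit(line, "[[:space:]]+")[[1]]
  pairs <- pairs[grepl("=", pairs, fixed = TRUE)]
  info <- list()
  for (p in pairs) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    val <- paste(kv[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(val))
    info[[kv[1]]] <- if (!is.na(num)) num else val
  }
  info
}

#' Convert a phase-space state to an XYZ frame
#'
#' Flat coordinates are packed row-wise into 3-vectors (zero-padded);
#' useful for dumping generic-DOF model states alongside bath particles.
#'
#' @param state A `phase_space_state`.
#' @param symbols Optional atom symbols (default `"X"` for solute sites,
#'   `"O"` for bath sites when a partition is present).
#' @param info Optional named list for the comment line; `time` is added
#'   automatically.
#' @return A frame list as consumed by [write_xyz()].
#' @export
state_to_frame <- function(state, symbols = NULL, info = list()) {
  x <- state$positions
  n_atoms <- ceiling(length(x) / 3)
  coords <- matrix(c(x, numeric(3 * n_atoms - length(x))), n_atoms, 3,
                   byrow = TRUE)
  if (is.null(symbols)) {
    symbols <- rep("X", n_atoms)
    if (!is.null(state$partition)) {
      n_qm_atoms <- ceiling(length(state$partition$qm_indices) / 3)
      if (n_qm_atoms < n_atoms)
        symbols[(n_qm_atoms + 1L):n_atoms] <- "O"
    }
  }
  info$time <- state$time
  list(symbols = symbols, coords = coords, info = info)
}
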