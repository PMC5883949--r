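#' Read trajectory frames
#'
#' Loads a multi-frame coordinate set and returns the frames whose time
#' stamp lies in `[begin, end]`, taking every `stride`-th stored frame of
#' that window. Supported formats:
#' \describe{
#'   \item{plain}{the package's text frame format: a header line
#'     `t <time_ps>` followed by one `x y z` line per atom (nm), frames
#'     concatenated.}
#'   \item{pdb}{multi-model PDB (MODEL/ENDMDL); coordinates are converted
#'     from Angstrom to nm. Frame times are synthesized as
#'     `frame_index * dt` (the PDB format carries none).}
#'   \item{dcd}{binary DCD via \pkg{bio3d}; times synthesized from `dt`.}
#' }
#' Distances downstream are plain Euclidean: trajectories are expected to be
#' pre-processed so molecules are whole (no periodic-image handling).
#'
#' @param path trajectory file.
#' @param topology matching `"topology"` object (atom counts must agree).
#' @param format `"auto"`, `"plain"`, `"pdb"` or `"dcd"`.
#' @param begin,end time window in ps (inclusive).
#' @param stride keep every stride-th frame of the window (>= 1).
#' @param dt fallback frame spacing in ps for formats without times.
#' @return Object of class `"traj"`: list with `coords`
#'   (`n_atoms x 3 x n_frames` array, nm), `times` (ps), `n_frames`.
#' @export
read_frames <- function(path, topology, format = c("auto", "plain", "pdb", "dcd"),
                        begin = -Inf, end = Inf, stride = 1L, dt = 1.0) {
  format <- match.arg(format)
  stopifnot(inherits(topology, "topology"))
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (begin > end) stop("begin must be <= end")
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be an integer >= 1")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", dcd = "dcd", "plain")
  }
  raw <- switch(format,
    plain = read_plain_traj(path),
    pdb = read_pdb_traj(path, dt),
    dcd = read_dcd_traj(path, dt)
  )
  n_atoms <- nrow(topology$atoms)
  if (dim(raw$coords)[1] != n_atoms) {
    stop("atom count mismatch: trajectory has ", dim(raw$coords)[1],
         " atoms, topology has ", n_atoms)
  }
  if (any(diff(raw$times) <= 0)) stop("frame times are not strictly increasing")
  keep <- which(raw$times >= begin & raw$times <= end)
  keep <- keep[seq(1L, length(keep), by = stride)]
  structure(list(
    coords = raw$coords[, , keep, drop = FALSE],
    times = raw$times[keep],
    n_frames = length(keep)
  ), class = "traj")
}

read_plain_traj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- startsWith(lines, "t ") | startsWith(lines, "t\t")
  if (!any(hdr)) stop("no 't <time>' frame headers found in ", path)
  times <- as.numeric(sub("^t[ \t]+", "", lines[hdr]))
  if (anyNA(times)) stop("malformed frame time header in ", path)
  n_frames <- length(times)
  body <- lines[!hdr]
  if (length(body) %% n_frames != 0L) {
    stop("inconsistent frame sizes in ", path, ": ", length(body),
         " coordinate lines across ", n_frames, " frames")
  }
  n_atoms <- length(body) %/% n_frames
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "[ \t]+"))))
  if (anyNA(vals) || length(vals) != 3L * n_atoms * n_frames) {
    stop("malformed coordinate line in ", path)
  }
  # body rows are atom-major within frame: reshape to atoms x 3 x frames
  coords <- aperm(array(vals, dim = c(3L, n_atoms, n_frames)), c(2L, 1L, 3L))
  list(coords = coords, times = times)
}

read_pdb_traj <- function(path, dt) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) %/% 3L
  coords <- array(NA_real_, dim = c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  }
  list(coords = coords, times = (seq_len(n_frames) - 1) * dt)
}

read_dcd_traj <- function(path, dt) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) %/% 3L
  coords <- array(NA_real_, dim = c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  }
  list(coords = coords, times = (seq_len(n_frames) - 1) * dt)
}

#' Write the plain text frame format
#'
#' @param coords `n_atoms x 3 x n_frames` array (nm).
#' @param times numeric vector of frame times (ps).
#' @param path output file.
#' @export
write_plain_traj <- function(coords, times, path) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == length(times))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(times)) {
    writeLines(sprintf("t %.6f", times[f]), con)
    m <- coords[, , f, drop = FALSE]
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1, 1], m[, 2, 1], m[, 3, 1]), con)
  }
  invisible(path)
}

#' @export
print.traj <- function(x, ...) {
  cat("trajectory:", x$n_frames, "frames,", dim(x$coords)[1], "atoms, t = [",
      if (x$n_frames) min(x$times) else NA, ",",
      if (x$n_frames) max(x$times) else NA, "] ps\n")
  invisible(x)
}
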