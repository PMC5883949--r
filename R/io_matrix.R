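#' Write a residue matrix in three-column plotting format
#'
#' The gnuplot-style layout: `i j value` lines (1-based residue indices),
#' row blocks separated by blank lines, preceded by a `#` header that
#' records the matrix size, the value semantics and the sentinel
#' conventions, so the file is self-describing and re-readable.
#'
#' Sentinels: `nan` on the diagonal; distance maps carry `r_cut` for pairs
#' never live; encounter maps carry `-1` (never in contact) and, for last
#' encounters, `-2` (persistent: still in contact at the final frame).
#'
#' @param M square numeric matrix (NA written as `nan`).
#' @param path output file.
#' @param semantics short description recorded in the header.
#' @param sentinel named character vector appended to the header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path, semantics = "value",
                         sentinel = c(diagonal = "nan")) {
  n <- nrow(M)
  stopifnot(n == ncol(M))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_residues %d", n),
    sprintf("# semantics %s", semantics),
    sprintf("# sentinel %s = %s", names(sentinel), sentinel),
    "# columns: i j value (1-based residue indices)"
  ), con)
  for (i in seq_len(n)) {
    v <- M[i, ]
    writeLines(sprintf("%d %d %s", i, seq_len(n),
                       ifelse(is.na(v), "nan", sprintf("%.6g", v))), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a three-column matrix file
#'
#' @param path file written by [write_matrix()].
#' @return the square numeric matrix (with `NA` where `nan` was written);
#'   header fields in attributes `n_residues` and `semantics`.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  n_line <- grep("^# n_residues ", hdr, value = TRUE)
  if (!length(n_line)) stop("missing '# n_residues' header in ", path)
  n <- as.integer(sub("^# n_residues ", "", n_line[1]))
  parts <- strsplit(trimws(body), "[ \t]+")
  if (any(lengths(parts) != 3L)) stop("malformed matrix line in ", path)
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  M <- matrix(NA_real_, n, n)
  M[cbind(as.integer(m[, 1]), as.integer(m[, 2]))] <-
    suppressWarnings(as.numeric(m[, 3]))
  sem <- sub("^# semantics ", "", grep("^# semantics ", hdr, value = TRUE))
  structure(M, n_residues = n,
            semantics = if (length(sem)) sem[1] else NA_character_)
}

#' Write the per-pair aggregate table
#'
#' Tab-separated columns `pair_i pair_j mean std min fraction first_ps
#' last_ps persistent` (1-based residues, distances nm, times ps).
#'
#' @param map an `"aggregate_map"`.
#' @param path output file.
#' @export
write_pair_table <- function(map, path) {
  df <- data.frame(pair_i = map$i, pair_j = map$j,
                   mean = sprintf("%.6g", map$mean),
                   std = sprintf("%.6g", map$sd),
                   min = sprintf("%.6g", map$min),
                   fraction = sprintf("%.6g", map$fraction),
                   first_ps = ifelse(is.na(map$first_ps), "nan",
                                     sprintf("%.6g", map$first_ps)),
                   last_ps = ifelse(is.na(map$last_ps), "nan",
                                    sprintf("%.6g", map$last_ps)),
                   persistent = ifelse(map$persistent, "yes", "no"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
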