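#' Pearson correlation of pair distances with time
#'
#' Per live pair, the Pearson correlation between the clamped distance
#' series and the frame times. The sign convention is physical: negative
#' coefficients mean the pair approaches (contact formation), positive ones
#' mean it separates (rupture). Pairs whose distance series has zero
#' variance are undefined and excluded (reported `NA`), never forced to 0.
#'
#' @param store a `"pair_store"` with at least 3 frames.
#' @param below_cutoff_only restrict each pair's series to frames with
#'   `d < r_cut` (drops the clamped plateau); pairs left with fewer than 3
#'   such frames become undefined.
#' @return `"pair_correlation"` data.frame with `i, j, r`, target attribute
#'   `"time"`.
#' @export
time_correlation <- function(store, below_cutoff_only = FALSE) {
  stopifnot(inherits(store, "pair_store"))
  if (store$n_frames < 3L) stop("need at least 3 frames for correlation")
  r <- pair_series_cor(store, store$times, below_cutoff_only)
  structure(data.frame(i = store$pairs$i, j = store$pairs$j, r = r),
            class = c("pair_correlation", "data.frame"),
            target = "time", n_residues = store$n_residues)
}

#' Pearson correlation of pair distances with an observable
#'
#' Correlates each live pair's clamped distance series with a scalar
#' time series (pulling force, radius of gyration, ...). Observable times
#' must match frame times within 1e-6 ps, or, with `nearest = TRUE`, each
#' frame is matched to the nearest observable sample.
#'
#' @param store a `"pair_store"`.
#' @param observable data.frame with columns `time` (ps) and `value`
#'   (see [read_observable()]).
#' @param nearest allow nearest-neighbor time matching.
#' @param name tag recorded for the observable.
#' @return `"pair_correlation"` data.frame with `i, j, r`.
#' @export
observable_correlation <- function(store, observable, nearest = FALSE,
                                   name = "observable") {
  stopifnot(inherits(store, "pair_store"),
            all(c("time", "value") %in% names(observable)))
  if (store$n_frames < 3L) stop("need at least 3 frames for correlation")
  if (nearest) {
    idx <- vapply(store$times, function(t) which.min(abs(observable$time - t)),
                  integer(1))
    y <- observable$value[idx]
  } else {
    if (nrow(observable) != store$n_frames ||
        any(abs(observable$time - store$times) > 1e-6)) {
      stop("observable times do not match frame times (tolerance 1e-6 ps); ",
           "use nearest = TRUE for nearest-neighbor matching")
    }
    y <- observable$value
  }
  r <- pair_series_cor(store, y, FALSE)
  structure(data.frame(i = store$pairs$i, j = store$pairs$j, r = r),
            class = c("pair_correlation", "data.frame"),
            target = name, n_residues = store$n_residues)
}

# rowwise Pearson against a common series; NA where either side has zero
# variance (stats::cor would warn and return NA; we pre-check to keep the
# undefined-vs-zero distinction explicit)
pair_series_cor <- function(store, y, below_cutoff_only) {
  v <- store$values
  vapply(seq_len(nrow(v)), function(p) {
    x <- v[p, ]
    yy <- y
    if (below_cutoff_only) {
      keep <- x < store$cutoffs$r_cut
      x <- x[keep]; yy <- yy[keep]
    }
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(yy) == 0) {
      return(NA_real_)
    }
    stats::cor(x, yy)
  }, numeric(1))
}

#' Read a two-column time/observable series
#'
#' Whitespace-separated `time_ps value` lines; comment lines starting with
#' `#` or `@` are ignored (xvg-compatible).
#'
#' @param path file path.
#' @return data.frame with columns `time`, `value`.
#' @export
read_observable <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#") & !startsWith(ln, "@")]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(ln, "[ \t]+"))))
  if (anyNA(vals) || length(vals) %% 2L != 0L) {
    stop("malformed observable file (expect two numeric columns): ", path)
  }
  m <- matrix(vals, ncol = 2L, byrow = TRUE)
  data.frame(time = m[, 1], value = m[, 2])
}

#' Per-residue contact count series
#'
#' `n_i(t)`: the number of live pairs involving residue `i` whose
#' hysteretic state is on at frame `t`. Inert or never-live residues give
#' all-zero rows.
#'
#' @param timeline a `"contact_timeline"`.
#' @param n_residues total residue count; defaults to the timeline's.
#' @return integer matrix `n_residues x n_frames`.
#' @export
contact_counts <- function(timeline, n_residues = timeline$n_residues) {
  stopifnot(inherits(timeline, "contact_timeline"))
  st <- timeline$states
  counts <- matrix(0L, n_residues, ncol(st))
  for (p in seq_len(nrow(st))) {
    on <- st[p, ]
    counts[timeline$pairs$i[p], ] <- counts[timeline$pairs$i[p], ] + on
    counts[timeline$pairs$j[p], ] <- counts[timeline$pairs$j[p], ] + on
  }
  counts
}

#' Residue-residue cross-correlation of contact counts
#'
#' Pearson correlation between the contact-count series of every residue
#' pair: `C[i, j] = cor(n_i(t), n_j(t))`. This replaces fluctuation-based
#' dynamic cross-correlation without any interframe fitting. Residues with
#' constant counts yield undefined (`NA`) rows/columns; the diagonal is 1
#' for residues with varying counts.
#'
#' @param counts matrix from [contact_counts()].
#' @return `"residue_crosscor"`: list with `C` (symmetric matrix) and
#'   `counts`.
#' @export
cross_correlation <- function(counts) {
  if (ncol(counts) < 3L) stop("need at least 3 frames for cross-correlation")
  varying <- apply(counts, 1, stats::sd) > 0
  n <- nrow(counts)
  C <- matrix(NA_real_, n, n)
  if (any(varying)) {
    C[varying, varying] <- stats::cor(t(counts[varying, , drop = FALSE]))
  }
  structure(list(C = C, counts = counts), class = "residue_crosscor")
}

#' @export
print.residue_crosscor <- function(x, ...) {
  cat("contact-count cross-correlation:", nrow(x$C), "residues,",
      sum(!is.na(diag(x$C))), "with varying counts\n")
  invisible(x)
}
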