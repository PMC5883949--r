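# internal constructor shared by aggregate() and economy-mode streaming
new_aggregate_map <- function(i, j, mean, sd, min, fraction, first_ps, last_ps,
                              persistent, n_frames, n_residues, cutoffs,
                              final_time) {
  out <- data.frame(i = i, j = j, mean = mean, sd = sd, min = min,
                    fraction = fraction, first_ps = first_ps,
                    last_ps = last_ps, persistent = persistent)
  structure(out, class = c("aggregate_map", "data.frame"),
            n_frames = n_frames, n_residues = n_residues, cutoffs = cutoffs,
            final_time = final_time)
}

#' Per-pair aggregate statistics
#'
#' Summarizes each live pair over the whole trajectory: mean and standard
#' deviation of the clamped distance (the contact analogue of coordinate
#' RMSF), minimum distance, hysteretic contact fraction, and first/last
#' encounter times. The standard deviation uses the population (1/N)
#' convention. Pairs still in contact at the final frame are flagged
#' `persistent`, so an unbroken contact is never misread as a late rupture.
#'
#' @param store a `"pair_store"` (full mode). Economy-mode
#'   [build_pair_store()] returns this object directly.
#' @param timeline optional precomputed [contact_states()] result; computed
#'   from the store's own cutoffs when absent.
#' @return `"aggregate_map"`: a data.frame with one row per live pair and
#'   columns `i, j, mean, sd, min, fraction, first_ps, last_ps, persistent`,
#'   plus attributes `n_frames`, `n_residues`, `cutoffs`, `final_time`.
#' @export
aggregate_map <- function(store, timeline = NULL) {
  stopifnot(inherits(store, "pair_store"))
  if (is.null(timeline)) timeline <- contact_states(store)
  v <- store$values
  mu <- rowMeans(v)
  sdv <- sqrt(rowMeans((v - mu)^2))
  enc <- encounter_times(timeline)
  new_aggregate_map(
    i = store$pairs$i, j = store$pairs$j,
    mean = mu, sd = sdv, min = apply(v, 1, min),
    fraction = rowMeans(timeline$states),
    first_ps = enc$first_ps, last_ps = enc$last_ps,
    persistent = enc$persistent,
    n_frames = store$n_frames, n_residues = store$n_residues,
    cutoffs = store$cutoffs, final_time = store$times[store$n_frames]
  )
}

#' First and last encounter times
#'
#' For every pair of a contact timeline, the time of the first and the last
#' frame in which the hysteretic state is on. In a pulling trajectory the
#' last encounter is the pair's rupture (unfolding) time. Pairs never on
#' get `NA`; pairs on at the final frame are flagged persistent.
#'
#' @param timeline a `"contact_timeline"`.
#' @return data.frame with `i, j, first_ps, last_ps, persistent`.
#' @export
encounter_times <- function(timeline) {
  stopifnot(inherits(timeline, "contact_timeline"))
  st <- timeline$states
  n_p <- nrow(st)
  first_ps <- last_ps <- rep(NA_real_, n_p)
  persistent <- logical(n_p)
  for (p in seq_len(n_p)) {
    on <- which(st[p, ])
    if (length(on)) {
      first_ps[p] <- timeline$times[on[1]]
      last_ps[p] <- timeline$times[on[length(on)]]
      persistent[p] <- st[p, ncol(st)]
    }
  }
  data.frame(i = timeline$pairs$i, j = timeline$pairs$j,
             first_ps = first_ps, last_ps = last_ps, persistent = persistent)
}

#' Differential contact map between two time windows
#'
#' Per-pair mean clamped distance over window B minus the mean over window
#' A; antisymmetric under window swap. Windows are inclusive time ranges in
#' ps.
#'
#' @param store a `"pair_store"`.
#' @param window_a,window_b numeric length-2 vectors `c(t0, t1)`.
#' @return `"differential_map"` data.frame with `i, j, delta_mean`, plus
#'   window attributes.
#' @export
differential_map <- function(store, window_a, window_b) {
  stopifnot(inherits(store, "pair_store"),
            length(window_a) == 2L, length(window_b) == 2L)
  in_a <- store$times >= window_a[1] & store$times <= window_a[2]
  in_b <- store$times >= window_b[1] & store$times <= window_b[2]
  if (!any(in_a)) stop("window A [", window_a[1], ", ", window_a[2],
                       "] contains no frames")
  if (!any(in_b)) stop("window B [", window_b[1], ", ", window_b[2],
                       "] contains no frames")
  delta <- rowMeans(store$values[, in_b, drop = FALSE]) -
    rowMeans(store$values[, in_a, drop = FALSE])
  structure(data.frame(i = store$pairs$i, j = store$pairs$j,
                       delta_mean = delta),
            class = c("differential_map", "data.frame"),
            window_a = window_a, window_b = window_b,
            n_residues = store$n_residues)
}

#' Full square matrix view of a per-pair statistic
#'
#' Expands a per-pair table into the symmetric `n_residues x n_residues`
#' matrix used by the writers and plots. Pairs that were never live carry a
#' sentinel: `r_cut` for distance-valued maps, 0 for the contact fraction,
#' `NA` for encounter times. The diagonal is emitted as `NA`. In
#' last-encounter maps, pairs still in contact at the final frame carry the
#' persistent sentinel `-2` (broken contacts carry their rupture time, and
#' never-on pairs `-1`), mirroring maps that color only broken contacts.
#'
#' @param map an `"aggregate_map"` or `"differential_map"`.
#' @param statistic column to expand: one of `"mean"`, `"sd"`, `"min"`,
#'   `"fraction"`, `"first_ps"`, `"last_ps"`, `"delta_mean"`.
#' @param sentinels use the reserved numeric sentinels (-1 never, -2
#'   persistent) in encounter maps instead of `NA`/times-at-end.
#' @return symmetric numeric matrix.
#' @export
map_matrix <- function(map, statistic, sentinels = TRUE) {
  n <- attr(map, "n_residues")
  cutoffs <- attr(map, "cutoffs")
  fill <- if (statistic %in% c("mean", "sd", "min")) {
    if (statistic == "mean" || statistic == "min") cutoffs$r_cut else 0
  } else if (statistic == "fraction") 0 else
    if (statistic == "delta_mean") 0 else NA_real_
  M <- matrix(fill, n, n)
  val <- map[[statistic]]
  if (statistic %in% c("first_ps", "last_ps") && sentinels) {
    val[is.na(val)] <- -1
    if (statistic == "last_ps") val[map$persistent] <- -2
    M[] <- -1
  }
  idx1 <- cbind(map$i, map$j)
  M[idx1] <- val
  M[idx1[, 2:1, drop = FALSE]] <- val
  diag(M) <- NA_real_
  M
}

#' @export
print.aggregate_map <- function(x, ...) {
  cat("aggregate map:", nrow(x), "live pairs over", attr(x, "n_frames"),
      "frames (", attr(x, "n_residues"), "residues )\n")
  NextMethod()
}
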