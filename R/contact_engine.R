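#' Cutoff scheme for contact detection
#'
#' Three cutoffs govern the contact analysis (all in nm):
#' \describe{
#'   \item{r_cut}{main cutoff. A residue pair with no atom pair ever
#'     strictly below `r_cut` is disregarded entirely; stored distances are
#'     clamped at `r_cut`.}
#'   \item{r_inter}{a contact forms when the pair distance drops strictly
#'     below `r_inter`.}
#'   \item{r_inter_high}{a contact breaks only when the distance rises
#'     strictly above `r_inter_high`. Choosing `r_inter_high > r_inter`
#'     gives hysteresis that suppresses flicker from outlier frames; with
#'     `r_inter_high == r_inter` the rule reduces to simple thresholding.}
#' }
#' Defaults: `r_cut = 1.0`, `r_inter = r_inter_high = 0.5`.
#'
#' @param r_cut,r_inter,r_inter_high cutoffs in nm; must satisfy
#'   `0 < r_inter <= r_inter_high <= r_cut`.
#' @return object of class `"cutoff_scheme"`.
#' @export
cutoff_scheme <- function(r_cut = 1.0, r_inter = 0.5, r_inter_high = r_inter) {
  if (!(r_inter > 0 && r_inter <= r_inter_high && r_inter_high <= r_cut)) {
    stop("cutoffs must satisfy 0 < r_inter <= r_inter_high <= r_cut ",
         sprintf("(got r_inter=%g, r_inter_high=%g, r_cut=%g)",
                 r_inter, r_inter_high, r_cut))
  }
  structure(list(r_cut = r_cut, r_inter = r_inter,
                 r_inter_high = r_inter_high), class = "cutoff_scheme")
}

# Dense n_res x n_res matrix of minimum selected-atom distances for one
# frame; Inf where either residue is inert; diagonal Inf.
frame_min_dist <- function(frame_coords, selection) {
  n_res <- length(selection$atoms)
  act <- which(!selection$inert)
  M <- matrix(Inf, n_res, n_res)
  if (length(act) < 2L) return(M)
  idx <- unlist(selection$atoms[act], use.names = FALSE)
  res_of <- rep.int(act, lengths(selection$atoms[act]))
  xyz <- frame_coords[idx, , drop = FALSE]
  D <- as.matrix(stats::dist(xyz))
  for (ai in seq_along(act)) {
    i <- act[ai]
    ri <- which(res_of == i)
    for (aj in seq_along(act)) {
      if (aj <= ai) next
      j <- act[aj]
      M[i, j] <- M[j, i] <- min(D[ri, res_of == j])
    }
  }
  M
}

#' Minimum interresidue distance in one frame
#'
#' The minimum Euclidean distance over all selected-atom pairs of two
#' residues (exhaustive over the cross product of the two atom groups; no
#' approximation).
#'
#' @param frame_coords `n_atoms x 3` coordinate matrix (nm).
#' @param selection a `"selection_map"`.
#' @param i,j distinct 1-based residue indices; both must be non-inert.
#' @return distance in nm.
#' @export
min_residue_distance <- function(frame_coords, selection, i, j) {
  if (i == j) stop("i and j must name distinct residues")
  if (selection$inert[i] || selection$inert[j]) {
    stop("residue pair (", i, ", ", j, ") involves an inert residue")
  }
  ai <- frame_coords[selection$atoms[[i]], , drop = FALSE]
  aj <- frame_coords[selection$atoms[[j]], , drop = FALSE]
  # difference-based form: bit-identical to an exhaustive atom-pair loop
  best <- Inf
  for (a in seq_len(nrow(ai))) {
    d2 <- (aj[, 1] - ai[a, 1])^2 + (aj[, 2] - ai[a, 2])^2 +
      (aj[, 3] - ai[a, 3])^2
    best <- min(best, d2)
  }
  sqrt(best)
}

#' Build the sparse live-pair distance store
#'
#' Single pass over the trajectory. Per frame, minimum interresidue
#' distances are computed for every admissible pair (sequence separation
#' `|i-j| >= min_seq_separation`); a pair becomes "live" the first time its
#' distance falls strictly below `r_cut`. Stored values are the clamped
#' distances `min(d, r_cut)` — frames at or beyond the cutoff hold exactly
#' `r_cut`.
#'
#' In `mode = "economy"` no per-frame values are retained: only streaming
#' aggregates (mean, population sd, min, hysteretic contact fraction,
#' first/last encounter) are accumulated, with memory independent of the
#' frame count, and an [aggregate_map] is returned directly.
#'
#' @param traj a `"traj"` object.
#' @param selection a `"selection_map"`.
#' @param cutoffs a `"cutoff_scheme"`.
#' @param min_seq_separation minimum `|i-j|` for a pair to be considered;
#'   the default 1 excludes only the diagonal, keeping the near-diagonal
#'   secondary-structure signal.
#' @param mode `"full"` (store every frame) or `"economy"` (streaming
#'   aggregates only).
#' @param precision significant decimal digits retained in stored values
#'   (`NULL` = full double precision). Aggregates are always accumulated at
#'   full precision; the default 4 guarantees at least 3 significant digits,
#'   mirroring half-precision storage economy.
#' @return `"pair_store"` (full mode) with fields `pairs` (data.frame `i`,
#'   `j`, 1-based, i < j), `values` (`n_pairs x n_frames` clamped nm),
#'   `times`, `cutoffs`, `n_residues`; or an `"aggregate_map"` (economy).
#' @export
build_pair_store <- function(traj, selection, cutoffs = cutoff_scheme(),
                             min_seq_separation = 1L,
                             mode = c("full", "economy"), precision = 4L) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "traj"), inherits(selection, "selection_map"),
            inherits(cutoffs, "cutoff_scheme"))
  if (traj$n_frames < 1L) stop("trajectory has no frames")
  n_res <- length(selection$atoms)
  n_f <- traj$n_frames
  r_cut <- cutoffs$r_cut
  sep_ok <- abs(outer(seq_len(n_res), seq_len(n_res), "-")) >= min_seq_separation

  if (mode == "full") {
    per_frame <- vector("list", n_f)
    live <- matrix(FALSE, n_res, n_res)
    for (f in seq_len(n_f)) {
      M <- frame_min_dist(traj$coords[, , f], selection)
      live <- live | (M < r_cut & sep_ok)
      per_frame[[f]] <- pmin(M, r_cut)
    }
    ut <- upper.tri(live)
    sel_pair <- which(live & ut, arr.ind = TRUE)
    ord <- order(sel_pair[, 1], sel_pair[, 2])
    sel_pair <- sel_pair[ord, , drop = FALSE]
    n_p <- nrow(sel_pair)
    if (n_p == 0L) warning("no live residue pairs under r_cut = ", r_cut)
    vals <- matrix(NA_real_, n_p, n_f)
    lin <- (sel_pair[, 2] - 1L) * n_res + sel_pair[, 1]
    for (f in seq_len(n_f)) vals[, f] <- per_frame[[f]][lin]
    if (!is.null(precision)) vals <- signif(vals, precision)
    return(structure(list(
      pairs = data.frame(i = unname(sel_pair[, 1]), j = unname(sel_pair[, 2])),
      values = vals,
      times = traj$times,
      n_frames = n_f,
      n_residues = n_res,
      cutoffs = cutoffs,
      min_seq_separation = as.integer(min_seq_separation)
    ), class = "pair_store"))
  }

  # economy: dense per-pair streaming accumulators, one resident frame
  cnt <- 0
  mean_m <- matrix(0, n_res, n_res)
  m2_m <- matrix(0, n_res, n_res)
  min_m <- matrix(Inf, n_res, n_res)
  live <- matrix(FALSE, n_res, n_res)
  state <- matrix(FALSE, n_res, n_res)
  on_cnt <- matrix(0L, n_res, n_res)
  first_t <- matrix(NA_real_, n_res, n_res)
  last_t <- matrix(NA_real_, n_res, n_res)
  resident <- 0L; max_resident <- 0L
  for (f in seq_len(n_f)) {
    M <- pmin(frame_min_dist(traj$coords[, , f], selection), r_cut)
    resident <- resident + 1L
    max_resident <- max(max_resident, resident)
    cnt <- cnt + 1
    delta <- M - mean_m
    mean_m <- mean_m + delta / cnt
    m2_m <- m2_m + delta * (M - mean_m)
    min_m <- pmin(min_m, M)
    live <- live | (M < r_cut & sep_ok)
    form <- M < cutoffs$r_inter
    brk <- M > cutoffs$r_inter_high
    state <- form | (state & !brk)
    on_now <- state & sep_ok
    on_cnt <- on_cnt + on_now
    first_t[on_now & is.na(first_t)] <- traj$times[f]
    last_t[on_now] <- traj$times[f]
    rm(M); resident <- resident - 1L
  }
  ut <- upper.tri(live)
  sel_pair <- which(live & ut, arr.ind = TRUE)
  ord <- order(sel_pair[, 1], sel_pair[, 2])
  sel_pair <- sel_pair[ord, , drop = FALSE]
  lin <- (sel_pair[, 2] - 1L) * n_res + sel_pair[, 1]
  persistent <- (state & sep_ok)[lin]
  am <- new_aggregate_map(
    i = unname(sel_pair[, 1]), j = unname(sel_pair[, 2]),
    mean = mean_m[lin], sd = sqrt(pmax(0, m2_m[lin] / cnt)),
    min = min_m[lin], fraction = on_cnt[lin] / cnt,
    first_ps = first_t[lin], last_ps = last_t[lin],
    persistent = persistent,
    n_frames = n_f, n_residues = n_res, cutoffs = cutoffs,
    final_time = traj$times[n_f]
  )
  attr(am, "max_resident_frames") <- max_resident
  am
}

#' Hysteretic contact states
#'
#' Applies the dual-cutoff state machine to every live pair of a store:
#' the state at the first frame is `d < r_inter`; thereafter it switches on
#' when `d < r_inter` and off when `d > r_inter_high`, and is carried over
#' while `d` lies in `[r_inter, r_inter_high]` (a first frame in that band
#' starts off). With `r_inter == r_inter_high` this is plain thresholding.
#'
#' @param store a `"pair_store"`.
#' @param cutoffs cutoff scheme; defaults to the store's own.
#' @return `"contact_timeline"`: list with `states` (logical
#'   `n_pairs x n_frames`), `pairs`, `times`, `n_residues`.
#' @export
contact_states <- function(store, cutoffs = store$cutoffs) {
  stopifnot(inherits(store, "pair_store"))
  v <- store$values
  n_p <- nrow(v)
  st <- matrix(FALSE, n_p, ncol(v))
  if (n_p > 0L && ncol(v) > 0L) {
    st[, 1] <- v[, 1] < cutoffs$r_inter
    if (ncol(v) > 1L) {
      for (f in 2:ncol(v)) {
        form <- v[, f] < cutoffs$r_inter
        brk <- v[, f] > cutoffs$r_inter_high
        st[, f] <- form | (st[, f - 1L] & !brk)
      }
    }
  }
  structure(list(states = st, pairs = store$pairs, times = store$times,
                 n_residues = store$n_residues),
            class = "contact_timeline")
}

#' @export
print.pair_store <- function(x, ...) {
  cat("pair store:", nrow(x$pairs), "live pairs x", x$n_frames, "frames;",
      "r_cut =", x$cutoffs$r_cut, "nm\n")
  invisible(x)
}

#' Assemble a pair store from explicit distance series
#'
#' Programmatic constructor, mainly for scripted distance schedules: takes
#' clamped per-pair distance series directly instead of a trajectory.
#'
#' @param values `n_pairs x n_frames` numeric matrix of distances (nm).
#' @param times frame times (ps); default `0:(n_frames-1)`.
#' @param pairs data.frame with columns `i`, `j` (1-based, i < j); default
#'   consecutive pairs.
#' @param cutoffs a `"cutoff_scheme"`; values are clamped to its `r_cut`.
#' @param n_residues total residue count; default `max(pairs$j)`.
#' @return a `"pair_store"`.
#' @export
pair_store <- function(values, times = NULL, pairs = NULL,
                       cutoffs = cutoff_scheme(), n_residues = NULL) {
  values <- rbind(values)
  if (is.null(times)) times <- seq_len(ncol(values)) - 1
  if (is.null(pairs)) {
    pairs <- data.frame(i = seq_len(nrow(values)), j = seq_len(nrow(values)) + 1L)
  }
  stopifnot(nrow(pairs) == nrow(values), all(pairs$i < pairs$j),
            length(times) == ncol(values))
  if (is.null(n_residues)) n_residues <- max(pairs$j)
  structure(list(
    pairs = pairs, values = pmin(values, cutoffs$r_cut), times = times,
    n_frames = ncol(values), n_residues = n_residues, cutoffs = cutoffs,
    min_seq_separation = 1L
  ), class = "pair_store")
}
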