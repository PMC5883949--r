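#' Generate a synthetic topology/trajectory fixture
#'
#' Builds desk-scale test systems with exactly known contact kinetics and
#' writes them in the formats the readers consume (a PDB topology and a
#' plain-text trajectory). Residues are point clusters whose atoms share
#' the residue center's x and z and are spread along y by a fixed 0.05 nm
#' ladder; because every residue uses the same ladder, the minimum
#' interresidue atom distance equals the center-center distance exactly,
#' so each scenario's distance schedule holds exactly before noise.
#'
#' Scenarios:
#' \describe{
#'   \item{static}{residue pairs held at fixed distances: per pair-group,
#'     one pair in contact (0.4 nm), one live but out of contact (0.8 nm),
#'     one never live (1.2 nm), cycling. With `placement = "random"`,
#'     centers are drawn uniformly in a 2 nm box instead (for oracle
#'     tests).}
#'   \item{linear_drift}{the distance of pair (1,2) is linear in time,
#'     `d(t) = drift_d0 + drift_slope * t` (defaults 0.9 nm, -0.004 nm/ps:
#'     a steady contact formation); all other residues are static and far.}
#'   \item{two_state}{`n_switch_pairs` pairs (default 3) sit at 0.45 nm in
#'     state A and `0.45 + separation` (default separation 0.3 nm) in state
#'     B; frames take state A for the first half and B for the second.}
#'   \item{scripted_unfolding}{pair k of the schedule is in contact
#'     (0.4 nm) through its break frame and jumps to 1.5 nm afterwards;
#'     one extra pair stays in contact throughout (persistent). Default
#'     schedule: pair k breaks at frame 10k, k = 1..5.}
#'   \item{competitive_switch}{residue 1 alternates partners: near residue
#'     2 (0.45 nm) while far from residue 3, then vice versa, switching
#'     every `phase_len` frames — the contact counts of residues 2 and 3
#'     are perfectly anti-phased.}
#' }
#'
#' @param scenario one of the five scenario names.
#' @param dir output directory (created if needed).
#' @param n_residues,atoms_per_residue system size (some scenarios impose a
#'   minimum).
#' @param n_frames,dt trajectory length and frame spacing (ps).
#' @param noise_sigma per-axis Gaussian displacement of every atom, nm.
#' @param seed integer seed; fully determines the output.
#' @param placement `"paired"` (exact schedules) or `"random"` (static
#'   only).
#' @param separation,n_switch_pairs two_state geometry.
#' @param drift_d0,drift_slope linear_drift schedule (nm, nm/ps).
#' @param schedule scripted_unfolding: data.frame `i, j, break_frame`
#'   (0-based frames).
#' @param phase_len competitive_switch block length in frames.
#' @return list with `topology_path`, `trajectory_path`, `ground_truth`
#'   (scenario-dependent), and the resolved parameters.
#' @export
make_fixture <- function(scenario = c("static", "linear_drift", "two_state",
                                      "scripted_unfolding", "competitive_switch"),
                         dir = tempfile("fixture"),
                         n_residues = 10L, atoms_per_residue = 4L,
                         n_frames = 10L, dt = 1.0, noise_sigma = 0,
                         seed = 1L, placement = c("paired", "random"),
                         separation = 0.3, n_switch_pairs = 3L,
                         drift_d0 = 0.9, drift_slope = -0.004,
                         schedule = NULL, phase_len = 5L) {
  scenario <- match.arg(scenario)
  placement <- match.arg(placement)
  stopifnot(noise_sigma >= 0, n_frames >= 1, atoms_per_residue >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  gt <- list(scenario = scenario, dt = dt, noise_sigma = noise_sigma)
  times <- (seq_len(n_frames) - 1) * dt

  # centers[r, axis, frame]
  centers <- array(0, dim = c(n_residues, 3L, n_frames))
  far <- function(r) c(0, 0, 100 + 5 * r)  # parked far from everything

  if (scenario == "static") {
    if (placement == "random") {
      with_seed(seed, {
        pos <- matrix(stats::runif(n_residues * 3L, 0, 2), n_residues, 3L)
      })
      for (f in seq_len(n_frames)) centers[, , f] <- pos
      gt$centers <- pos
    } else {
      # groups of 2 residues at cycling gaps 0.4 / 0.8 / 1.2 nm
      gaps <- c(0.4, 0.8, 1.2)
      pos <- matrix(0, n_residues, 3L)
      for (r in seq_len(n_residues)) {
        g <- (r - 1L) %/% 2L
        pos[r, ] <- c(if (r %% 2L == 0L) gaps[(g %% 3L) + 1L] else 0, 0, 3 * g)
      }
      for (f in seq_len(n_frames)) centers[, , f] <- pos
      gt$centers <- pos
      gt$pair_distance <- as.matrix(stats::dist(pos))
    }
  } else if (scenario == "linear_drift") {
    if (n_residues < 2L) stop("linear_drift needs >= 2 residues")
    d <- drift_d0 + drift_slope * times
    if (any(d <= 0)) stop("drift schedule reaches non-positive distances")
    for (f in seq_len(n_frames)) {
      centers[2, 1, f] <- d[f]
      for (r in seq_len(n_residues)[-(1:2)]) centers[r, , f] <- far(r)
    }
    gt$drift_pair <- c(1L, 2L)
    gt$distance <- d
    gt$expected_r <- if (drift_slope > 0) 1 else -1
  } else if (scenario == "two_state") {
    need <- 2L * n_switch_pairs
    if (n_residues < need) stop("two_state needs >= ", need, " residues")
    states <- c(rep(0L, ceiling(n_frames / 2)), rep(1L, floor(n_frames / 2)))
    dA <- 0.45; dB <- 0.45 + separation
    for (f in seq_len(n_frames)) {
      for (p in seq_len(n_switch_pairs)) {
        a <- 2L * p - 1L; b <- 2L * p
        centers[a, , f] <- c(0, 0, 3 * (p - 1))
        centers[b, , f] <- c(if (states[f] == 0L) dA else dB, 0, 3 * (p - 1))
      }
      for (r in seq_len(n_residues)[-(seq_len(need))]) centers[r, , f] <- far(r)
    }
    gt$states <- states
    gt$switch_pairs <- data.frame(i = 2L * seq_len(n_switch_pairs) - 1L,
                                  j = 2L * seq_len(n_switch_pairs))
    gt$separation <- separation
  } else if (scenario == "scripted_unfolding") {
    if (is.null(schedule)) {
      schedule <- data.frame(i = 2L * (1:5) - 1L, j = 2L * (1:5),
                             break_frame = 10L * (1:5))
    }
    n_sched <- nrow(schedule)
    need <- max(schedule$j) + 2L  # + one persistent pair
    if (n_residues < need) n_residues <- need
    if (n_frames <= max(schedule$break_frame) + 1L) {
      stop("n_frames must exceed the last break frame + 1")
    }
    centers <- array(0, dim = c(n_residues, 3L, n_frames))
    used <- unique(c(schedule$i, schedule$j))
    for (f in seq_len(n_frames)) {
      f0 <- f - 1L  # 0-based frame index
      for (s in seq_len(n_sched)) {
        a <- schedule$i[s]; b <- schedule$j[s]
        z <- 3 * (s - 1)
        centers[a, , f] <- c(0, 0, z)
        centers[b, , f] <- c(if (f0 <= schedule$break_frame[s]) 0.4 else 1.5,
                             0, z)
      }
      # persistent pair: last two residues, always 0.4 nm apart
      z <- 3 * n_sched
      centers[n_residues - 1L, , f] <- c(0, 0, z)
      centers[n_residues, , f] <- c(0.4, 0, z)
      for (r in setdiff(seq_len(n_residues),
                        c(used, n_residues - 1L, n_residues))) {
        centers[r, , f] <- far(r)
      }
    }
    gt$schedule <- schedule
    gt$break_time <- schedule$break_frame * dt
    gt$persistent_pair <- c(n_residues - 1L, n_residues)
  } else { # competitive_switch
    if (n_residues < 3L) stop("competitive_switch needs >= 3 residues")
    phase <- ((seq_len(n_frames) - 1L) %/% phase_len) %% 2L
    for (f in seq_len(n_frames)) {
      centers[2, , f] <- c(-0.8, 0, 0)
      centers[3, , f] <- c(+0.8, 0, 0)
      centers[1, 1, f] <- if (phase[f] == 0L) -0.35 else +0.35
      for (r in seq_len(n_residues)[-(1:3)]) centers[r, , f] <- far(r)
    }
    gt$phase <- phase
    gt$partners <- c(A = 1L, B = 2L, C = 3L)
  }

  # expand centers to atoms: shared y-ladder, then optional noise
  y_off <- 0.05 * (seq_len(atoms_per_residue) - 1L)
  n_atoms <- n_residues * atoms_per_residue
  coords <- array(0, dim = c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    for (r in seq_len(n_residues)) {
      rows <- (r - 1L) * atoms_per_residue + seq_len(atoms_per_residue)
      coords[rows, 1, f] <- centers[r, 1, f]
      coords[rows, 2, f] <- centers[r, 2, f] + y_off
      coords[rows, 3, f] <- centers[r, 3, f]
    }
  }
  if (noise_sigma > 0) {
    with_seed(seed + 1L, {
      coords <- coords + array(stats::rnorm(length(coords), 0, noise_sigma),
                               dim = dim(coords))
    })
  }

  topo_path <- file.path(dir, "topology.pdb")
  traj_path <- file.path(dir, "trajectory.dat")
  write_fixture_pdb(coords[, , 1, drop = TRUE], n_residues, atoms_per_residue,
                    topo_path)
  write_plain_traj(coords, times, traj_path)
  list(topology_path = topo_path, trajectory_path = traj_path,
       ground_truth = gt, scenario = scenario, n_residues = n_residues,
       atoms_per_residue = atoms_per_residue, n_frames = n_frames, dt = dt,
       noise_sigma = noise_sigma, seed = seed, times = times,
       coords = coords)
}

# fixed-column PDB writer for fixture topologies (coordinates nm -> A)
write_fixture_pdb <- function(frame, n_residues, atoms_per_residue, path) {
  lines <- character(n_residues * atoms_per_residue)
  k <- 0L
  for (r in seq_len(n_residues)) {
    for (a in seq_len(atoms_per_residue)) {
      k <- k + 1L
      nm <- if (a == 1L) "CA" else sprintf("C%d", a)
      lines[k] <- sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        k, nm, " ", "ALA", "A", r, " ",
        frame[k, 1] * 10, frame[k, 2] * 10, frame[k, 3] * 10, 1, 0, "C")
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Expected statistics for a fixture
#'
#' Analytic expectations implied by a fixture's construction, with
#' tolerances scaled to the noise level: per-axis position noise of
#' standard deviation `s` on both atoms inflates a pair distance by
#' roughly `sqrt(2) * s` (first order), which is the basis of the
#' distance-level tolerances reported here.
#'
#' @param fixture result of [make_fixture()].
#' @return list of expected values and tolerances, by scenario.
#' @export
reference_stats <- function(fixture) {
  gt <- fixture$ground_truth
  s_d <- sqrt(2) * fixture$noise_sigma  # first-order distance noise
  out <- list(scenario = gt$scenario, distance_noise_sd = s_d)
  if (gt$scenario == "static" && !is.null(gt$pair_distance)) {
    out$mean_distance <- pmin(gt$pair_distance, 1.0)
    out$sd_distance <- 0
    out$tol_mean <- max(4 * s_d / sqrt(fixture$n_frames), 1e-9)
  } else if (gt$scenario == "linear_drift") {
    out$expected_r <- gt$expected_r
    out$tol_r <- if (fixture$noise_sigma == 0) 1e-12 else 0.05
    out$distance <- gt$distance
  } else if (gt$scenario == "two_state") {
    out$states <- gt$states
    out$expected_ari <- 1.0
    out$min_pc1_fraction <- 0.9
  } else if (gt$scenario == "scripted_unfolding") {
    out$schedule <- gt$schedule
    out$last_encounter_time <- gt$break_time
    out$persistent_pair <- gt$persistent_pair
  } else if (gt$scenario == "competitive_switch") {
    out$anticorrelated <- c(2L, 3L)
    out$expected_sign <- -1
  }
  out
}

# run code under a fixed RNG seed without touching global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
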