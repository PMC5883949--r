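test_that("cutoff schemes enforce the ordering invariant", {
  expect_silent(cutoff_scheme(1.0, 0.5, 0.6))
  expect_error(cutoff_scheme(1.0, 0.6, 0.5), "cutoffs")
  expect_error(cutoff_scheme(0.4, 0.5, 0.5), "cutoffs")
  expect_error(cutoff_scheme(1.0, 0), "cutoffs")
})

test_that("min_residue_distance reproduces hand geometry and rejects bad pairs", {
  # residue 1: one atom at origin; residue 2: atoms at 0.3 and 0.9 nm
  coords <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.9, 0, 0))
  sel <- structure(list(atoms = list(1L, 2:3), inert = c(FALSE, FALSE),
                        atom_class = "heavy"), class = "selection_map")
  expect_equal(min_residue_distance(coords, sel, 1, 2), 0.3)
  expect_error(min_residue_distance(coords, sel, 1, 1), "distinct")
  sel$inert[2] <- TRUE
  expect_error(min_residue_distance(coords, sel, 1, 2), "inert")
})

test_that("minimum distances equal the exhaustive double loop on random frames", {
  sel <- toy_selection(10, 4)
  for (s in 1:20) {
    fx <- make_fixture("static", n_residues = 10, atoms_per_residue = 4,
                       n_frames = 1, noise_sigma = 0.05, seed = s,
                       placement = "random")
    frame <- fx$coords[, , 1]
    for (i in 1:9) for (j in (i + 1):10) {
      expect_equal(min_residue_distance(frame, sel, i, j),
                   brute_min_dist(frame, sel, i, j), tolerance = 1e-12)
    }
  }
})

test_that("build_pair_store clamps and applies the live-pair rule", {
  # two residues fixed 0.4 nm apart for 5 frames -> one live pair, all 0.4
  coords <- array(0, dim = c(2, 3, 5))
  coords[2, 1, ] <- 0.4
  st <- build_pair_store(toy_traj(coords), toy_selection(2, 1))
  expect_equal(nrow(st$pairs), 1L)
  expect_equal(unname(st$values[1, ]), rep(0.4, 5))

  # fixed at 1.2 nm -> never live
  coords[2, 1, ] <- 1.2
  expect_warning(st <- build_pair_store(toy_traj(coords), toy_selection(2, 1)),
                 "no live")
  expect_equal(nrow(st$pairs), 0L)

  # 0.8 nm for frames 1..5 then 1.5 nm: values clamped at r_cut
  coords <- array(0, dim = c(2, 3, 10))
  coords[2, 1, ] <- c(rep(0.8, 5), rep(1.5, 5))
  st <- build_pair_store(toy_traj(coords), toy_selection(2, 1))
  expect_equal(unname(st$values[1, ]), c(rep(0.8, 5), rep(1.0, 5)))
})

test_that("a distance exactly at r_cut does not make a pair live", {
  coords <- array(0, dim = c(2, 3, 3))
  coords[2, 1, ] <- 1.0
  expect_warning(st <- build_pair_store(toy_traj(coords), toy_selection(2, 1)))
  expect_equal(nrow(st$pairs), 0L)
})

test_that("min_seq_separation excludes near-diagonal pairs", {
  # residues on a line at 0, 0.4, 0.8 nm: pairs (1,2),(2,3) adjacent,
  # (1,3) at separation 2 and distance 0.8 < r_cut
  coords <- array(0, dim = c(3, 3, 2))
  coords[2, 1, ] <- 0.4
  coords[3, 1, ] <- 0.8
  tr <- toy_traj(coords)
  sel <- toy_selection(3, 1)
  st1 <- build_pair_store(tr, sel, min_seq_separation = 1)
  st2 <- build_pair_store(tr, sel, min_seq_separation = 2)
  expect_equal(nrow(st1$pairs), 3L)
  expect_equal(st2$pairs, data.frame(i = 1L, j = 3L))
  expect_true(all(abs(st2$pairs$i - st2$pairs$j) >= 2))
})

test_that("stored precision keeps at least 3 significant digits", {
  coords <- array(0, dim = c(2, 3, 1))
  coords[2, 1, 1] <- 0.123456
  st <- build_pair_store(toy_traj(coords), toy_selection(2, 1))
  expect_equal(unname(st$values[1, 1]), 0.1235, tolerance = 1e-12)
  st_full <- build_pair_store(toy_traj(coords), toy_selection(2, 1),
                              precision = NULL)
  expect_equal(unname(st_full$values[1, 1]), 0.123456, tolerance = 1e-9)
})

test_that("hysteresis follows the dual-cutoff state machine", {
  cs <- function(d, ri, rh) {
    st <- pair_store(matrix(d, 1), cutoffs = cutoff_scheme(1.0, ri, rh))
    unname(contact_states(st)$states[1, ])
  }
  # the 0.55 excursion does not break the contact under 0.5/0.6
  expect_equal(cs(c(0.45, 0.55, 0.45), 0.5, 0.6), c(TRUE, TRUE, TRUE))
  # single-cutoff limit: plain thresholding
  expect_equal(cs(c(0.45, 0.55, 0.45), 0.5, 0.5), c(TRUE, FALSE, TRUE))
  # stepping through the machine from an off start in the dead band
  expect_equal(cs(c(0.7, 0.45, 0.55, 0.65, 0.45), 0.5, 0.6),
               c(FALSE, TRUE, TRUE, FALSE, TRUE))
  # first frame inside [r_inter, r_inter_high] starts off
  expect_equal(cs(c(0.55, 0.55), 0.5, 0.6), c(FALSE, FALSE))
})

test_that("dual cutoffs never break contacts more often than a single cutoff", {
  n_breaks <- function(states) sum(states[-length(states)] & !states[-1])
  set.seed(42)
  for (w in 1:200) {
    d <- 0.55 + cumsum(rnorm(50, 0, 0.05))
    d <- pmin(pmax(d, 0.05), 1.0)
    dual <- pair_store(matrix(d, 1), cutoffs = cutoff_scheme(1.0, 0.5, 0.6))
    single <- pair_store(matrix(d, 1), cutoffs = cutoff_scheme(1.0, 0.5, 0.5))
    expect_lte(n_breaks(contact_states(dual)$states[1, ]),
               n_breaks(contact_states(single)$states[1, ]))
  }
})

test_that("distances are invariant to atom order within residues", {
  fx <- make_fixture("static", n_residues = 6, atoms_per_residue = 4,
                     n_frames = 3, noise_sigma = 0.03, seed = 9,
                     placement = "random")
  sel <- toy_selection(6, 4)
  sel_rev <- sel
  sel_rev$atoms <- lapply(sel$atoms, rev)
  st <- build_pair_store(toy_traj(fx$coords), sel, precision = NULL)
  st_rev <- build_pair_store(toy_traj(fx$coords), sel_rev, precision = NULL)
  expect_identical(st$pairs, st_rev$pairs)
  expect_equal(st$values, st_rev$values, tolerance = 1e-15)
})

test_that("economy mode reproduces full-mode aggregates and stays streaming", {
  fx <- make_fixture("static", n_residues = 6, atoms_per_residue = 3,
                     n_frames = 200, noise_sigma = 0.02, seed = 13)
  topo <- load_topology(fx$topology_path)
  sel <- select_atoms(topo)
  tr <- read_frames(fx$trajectory_path, topo)
  full <- aggregate_map(build_pair_store(tr, sel))
  eco <- build_pair_store(tr, sel, mode = "economy")
  expect_s3_class(eco, "aggregate_map")
  expect_equal(eco$i, full$i)
  expect_equal(eco$j, full$j)
  expect_true(all(abs(eco$mean - full$mean) <= 0.002))
  expect_true(all(abs(eco$sd - full$sd) <= 0.005))
  expect_equal(eco$fraction, full$fraction)
  expect_equal(eco$first_ps, full$first_ps)
  expect_equal(eco$last_ps, full$last_ps)
  expect_equal(attr(eco, "max_resident_frames"), 1L)
})
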