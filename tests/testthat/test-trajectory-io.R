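test_that("PDB topologies parse with residues in file order", {
  p <- write_toy_pdb(tempfile(fileext = ".pdb"))
  topo <- load_topology(p)
  expect_equal(topo$n_residues, 2L)
  expect_equal(nrow(topo$atoms), 5L)
  expect_equal(topo$residues$name, c("ALA", "GLY"))
  expect_equal(topo$atoms$residue, c(1L, 1L, 1L, 1L, 2L))
  expect_equal(topo$atoms$index, 1:5)
})

test_that("multi-chain PDBs concatenate chains in file order", {
  p <- write_toy_pdb(tempfile(fileext = ".pdb"), chain2 = TRUE)
  topo <- load_topology(p)
  expect_equal(topo$residues$chain, c("A", "B"))
  expect_equal(topo$n_residues, 2L)
})

test_that("HETATM records form their own residues", {
  p <- tempfile(fileext = ".pdb")
  lines <- readLines(write_toy_pdb(tempfile(fileext = ".pdb")))
  het <- pdb_atom_line(6, "O", "HOH", "A", 3, 8.0, 0.0, 0.0, "O",
                       record = "HETATM")
  writeLines(c(lines[1:5], het, "END"), p)
  topo <- load_topology(p)
  expect_equal(topo$n_residues, 3L)
  expect_equal(topo$residues$name[3], "HOH")
})

test_that("malformed and degenerate topologies raise informative errors", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1", "END"), p)  # truncated record
  expect_error(load_topology(p), "line 1")
  writeLines("END", p)
  expect_error(load_topology(p), "no atoms")
  # insertion code
  lines <- readLines(write_toy_pdb(tempfile(fileext = ".pdb")))
  l <- lines[1]
  substr(l, 27, 27) <- "A"
  writeLines(c(l, "END"), p)
  expect_error(load_topology(p), "insertion")
})

test_that("alternate locations other than ' '/'A' are dropped with a warning", {
  p <- tempfile(fileext = ".pdb")
  lines <- readLines(write_toy_pdb(tempfile(fileext = ".pdb")))
  lb <- lines[2]
  substr(lb, 17, 17) <- "B"
  writeLines(c(lines[1], lb, lines[3:5], "END"), p)
  expect_warning(topo <- load_topology(p), "alternate-location")
  expect_equal(nrow(topo$atoms), 4L)
})

test_that("GRO dialect parses fixed columns", {
  p <- tempfile(fileext = ".gro")
  writeLines(c(
    "toy", "3",
    "    1ALA      N    1   0.000   0.000   0.000",
    "    1ALA     CA    2   0.100   0.000   0.000",
    "    2GLY     CA    3   0.500   0.000   0.000",
    "   2.0 2.0 2.0"), p)
  topo <- load_topology(p)
  expect_equal(topo$n_residues, 2L)
  expect_equal(topo$atoms$name, c("N", "CA", "CA"))
  expect_equal(topo$atoms$element, c("N", "C", "C"))
})

test_that("atom-class selections follow the class rules", {
  p <- write_toy_pdb(tempfile(fileext = ".pdb"))
  topo <- load_topology(p)
  expect_length(select_atoms(topo, "heavy")$atoms[[1]], 3L)   # N CA C
  expect_equal(select_atoms(topo, "c_alpha")$atoms[[1]], 2L)
  expect_length(select_atoms(topo, "all")$atoms[[1]], 4L)
  sc <- suppressMessages(select_atoms(topo, "side_chain"))
  expect_length(sc$atoms[[1]], 0L)  # toy ALA has no heavy side-chain atoms
  expect_true(sc$inert[1])
})

test_that("backbone and side chain partition the heavy atoms", {
  fx <- make_fixture("static", n_residues = 4, atoms_per_residue = 5,
                     n_frames = 1, seed = 3)
  topo <- load_topology(fx$topology_path)
  heavy <- select_atoms(topo, "heavy")
  bb <- select_atoms(topo, "backbone")
  sc <- suppressMessages(select_atoms(topo, "side_chain"))
  for (r in seq_len(topo$n_residues)) {
    expect_setequal(c(bb$atoms[[r]], sc$atoms[[r]]), heavy$atoms[[r]])
    expect_length(intersect(bb$atoms[[r]], sc$atoms[[r]]), 0L)
  }
})

test_that("restriction lists make excluded residues inert", {
  fx <- make_fixture("static", n_residues = 6, n_frames = 1, seed = 2)
  topo <- load_topology(fx$topology_path)
  rf <- tempfile()
  writeLines(c("# keep", "1", "2", "5"), rf)
  sel <- suppressMessages(select_atoms(topo, "heavy",
                                       restrict = read_restriction(rf)))
  expect_equal(which(!sel$inert), c(1L, 2L, 5L))
})

test_that("plain frame format round-trips within printed precision", {
  coords <- array(runif(5 * 3 * 4, 0, 2), dim = c(5, 3, 4))
  times <- c(0, 0.5, 1.2, 3.3)
  p <- tempfile()
  write_plain_traj(coords, times, p)
  topo <- structure(list(atoms = data.frame(index = 1:5), n_residues = 1,
                         residues = data.frame(chain = "A", seq = 1,
                                               name = "ALA")),
                    class = "topology")
  tr <- read_frames(p, topo, format = "plain")
  expect_equal(tr$times, times)
  expect_equal(tr$coords, coords, tolerance = 1e-6)
})

test_that("begin/end/stride frame selection matches direct enumeration", {
  fx <- make_fixture("static", n_residues = 4, n_frames = 10, seed = 5)
  topo <- load_topology(fx$topology_path)
  expect_equal(read_frames(fx$trajectory_path, topo)$n_frames, 10L)
  tr3 <- read_frames(fx$trajectory_path, topo, stride = 3)
  expect_equal(tr3$times, c(0, 3, 6, 9))
  # begin at the 5th stored frame's time -> 6 frames remain
  tr <- read_frames(fx$trajectory_path, topo, begin = fx$times[5])
  expect_equal(tr$n_frames, 6L)
  # property: count under stride s is ceil(n_selected / s)
  for (s in 1:5) {
    n_sel <- sum(fx$times >= 2 & fx$times <= 8)
    trs <- read_frames(fx$trajectory_path, topo, begin = 2, end = 8, stride = s)
    expect_equal(trs$n_frames, ceiling(n_sel / s))
  }
})

test_that("multi-model PDB trajectories read with Angstrom-to-nm conversion", {
  fx <- make_fixture("static", n_residues = 3, atoms_per_residue = 2,
                     n_frames = 3, seed = 11)
  topo <- load_topology(fx$topology_path)
  p <- tempfile(fileext = ".pdb")
  lines <- character(0)
  for (f in 1:3) {
    lines <- c(lines, sprintf("MODEL %8d", f))
    k <- 0
    for (r in 1:3) for (a in 1:2) {
      k <- k + 1
      lines <- c(lines, pdb_atom_line(k, "CA", "ALA", "A", r,
                                      fx$coords[k, 1, f] * 10,
                                      fx$coords[k, 2, f] * 10,
                                      fx$coords[k, 3, f] * 10, "C"))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), p)
  tr <- read_frames(p, topo, format = "pdb", dt = 2)
  expect_equal(tr$n_frames, 3L)
  expect_equal(tr$times, c(0, 2, 4))
  expect_equal(tr$coords, fx$coords, tolerance = 1e-4)
})

test_that("atom-count mismatches are a hard error", {
  fx <- make_fixture("static", n_residues = 4, n_frames = 2, seed = 1)
  topo <- load_topology(write_toy_pdb(tempfile(fileext = ".pdb")))
  expect_error(read_frames(fx$trajectory_path, topo), "atom count mismatch")
})
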