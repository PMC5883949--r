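# Independent oracles and small inline fixtures used across the suite.

# exhaustive double loop over all selected-atom pairs; deliberately naive
brute_min_dist <- function(frame, selection, i, j) {
  best <- Inf
  for (a in selection$atoms[[i]]) {
    for (b in selection$atoms[[j]]) {
      d <- sqrt((frame[a, 1] - frame[b, 1])^2 +
                  (frame[a, 2] - frame[b, 2])^2 +
                  (frame[a, 3] - frame[b, 3])^2)
      if (d < best) best <- d
    }
  }
  best
}

# textbook Pearson correlation, written from the definition
pearson_ref <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force inter-frame contact RMSD
brute_interframe_rmsd <- function(values) {
  n <- ncol(values); P <- nrow(values)
  D <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      D[a, b] <- sqrt(sum((values[, a] - values[, b])^2) / P)
    }
  }
  D
}

# canonical fixed-column ATOM/HETATM record (columns per the PDB standard)
pdb_atom_line <- function(no, name, res, chain, resno, x, y, z, elem,
                          altloc = " ", icode = " ", record = "ATOM  ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, no, name, altloc, res, chain, resno, icode,
          x, y, z, 1, 0, elem)
}

# a hand-written 2-residue, 5-atom PDB (alanine-like, with one hydrogen)
write_toy_pdb <- function(path, chain2 = FALSE) {
  lines <- c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.0, 0.0, 0.0, "C"),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.0, 0.0, 0.0, "C"),
    pdb_atom_line(4, "HA", "ALA", "A", 1, 1.0, 1.0, 0.0, "H"),
    pdb_atom_line(5, "CA", "GLY", if (chain2) "B" else "A", 2,
                  5.0, 0.0, 0.0, "C"),
    "END")
  writeLines(lines, path)
  path
}

# build a topology + selection directly for an in-memory coordinate matrix:
# n_res residues x n_atom atoms each, all heavy
toy_selection <- function(n_res, n_atom) {
  structure(list(
    atoms = split(seq_len(n_res * n_atom),
                  rep(seq_len(n_res), each = n_atom)),
    inert = rep(FALSE, n_res),
    atom_class = "heavy"
  ), class = "selection_map")
}

# traj object from a coords array
toy_traj <- function(coords, dt = 1.0) {
  structure(list(coords = coords, times = (seq_len(dim(coords)[3]) - 1) * dt,
                 n_frames = dim(coords)[3]), class = "traj")
}
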