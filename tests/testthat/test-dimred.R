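test_that("inter-frame RMSD matches closed forms and the brute-force oracle", {
  # identical frames -> all zeros
  st <- pair_store(matrix(0.5, 3, 4))
  expect_equal(interframe_rmsd(st)$D, matrix(0, 4, 4))
  # one pair, distances 0.4 vs 0.6 -> D = 0.2
  st <- pair_store(matrix(c(0.4, 0.6), 1))
  expect_equal(interframe_rmsd(st)$D[1, 2], 0.2)
  # random store vs double loop
  set.seed(41)
  v <- matrix(runif(7 * 10, 0.2, 1.0), 7)
  st <- pair_store(v)
  expect_equal(interframe_rmsd(st)$D, brute_interframe_rmsd(v),
               tolerance = 1e-10)
})

test_that("the inter-frame RMSD is a metric", {
  set.seed(42)
  v <- matrix(runif(5 * 30, 0.2, 1.0), 5)
  D <- interframe_rmsd(pair_store(v))$D
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 30))
  for (rep in 1:200) {
    abc <- sample(30, 3)
    expect_lte(D[abc[1], abc[3]],
               D[abc[1], abc[2]] + D[abc[2], abc[3]] + 1e-12)
  }
})

test_that("trivial clusterings behave: k = n and k out of range", {
  set.seed(43)
  v <- matrix(runif(4 * 6, 0.2, 1.0), 4)
  fd <- interframe_rmsd(pair_store(v))
  cl <- cluster_frames(fd, k = 6)
  expect_equal(sort(cl$labels), 0:5)
  expect_equal(cl$medoid[cl$labels + 1L], seq_len(6))
  expect_equal(cl$distance_to_medoid, rep(0, 6))
  expect_error(cluster_frames(fd, k = 7), "k must lie")
})

test_that("two-state trajectories are recovered exactly with medoid optimality", {
  skip_if_not_installed("mclust")
  for (s in c(1, 7, 23)) {
    fx <- make_fixture("two_state", n_frames = 60, noise_sigma = 0.01,
                       seed = s)
    topo <- load_topology(fx$topology_path)
    sel <- select_atoms(topo)
    st <- build_pair_store(read_frames(fx$trajectory_path, topo), sel)
    fd <- interframe_rmsd(st)
    cl <- cluster_frames(fd, k = 2)
    expect_equal(mclust::adjustedRandIndex(cl$labels, fx$ground_truth$states), 1)
    # medoids: exhaustive argmin of in-cluster distance sums
    for (c in 0:1) {
      members <- which(cl$labels == c)
      sums <- sapply(members, function(m) sum(fd$D[m, members]))
      expect_equal(cl$medoid[c + 1L], members[which.min(sums)])
    }
    # labels renumbered by first occurrence: frame 1 is cluster 0
    expect_equal(cl$labels[1], 0L)
  }
})

test_that("clustering is deterministic and cuts at height work", {
  set.seed(44)
  v <- matrix(runif(5 * 20, 0.2, 1.0), 5)
  fd <- interframe_rmsd(pair_store(v))
  cl1 <- cluster_frames(fd, k = 3)
  cl2 <- cluster_frames(fd, k = 3)
  expect_identical(cl1$labels, cl2$labels)
  clh <- cluster_frames(fd, h = max(cl1$height) + 1)
  expect_equal(clh$k, 1L)
})

test_that("PCA conserves variance and reconstructs the centered data", {
  set.seed(45)
  v <- matrix(runif(6 * 20, 0.2, 1.0), 6)
  st <- pair_store(v)
  pc <- pca_contacts(st)
  expect_lt(abs(sum(pc$eigenvalues) - pc$total_variance) /
              pc$total_variance, 1e-8)
  # full-basis reconstruction
  Xc <- t(v) - rep(1, 20) %o% pc$center
  expect_lt(max(abs(pc$projections %*% t(pc$loadings) - Xc)), 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
               tolerance = 1e-10)
  # all-identical frames -> all eigenvalues zero
  pc0 <- pca_contacts(pair_store(matrix(0.5, 3, 4)))
  expect_equal(pc0$eigenvalues, rep(0, 3))
  expect_error(pca_contacts(st, n_components = 50), "exceeds")
})

test_that("covariance and Gram routes give identical PCA results", {
  set.seed(46)
  v <- matrix(runif(12 * 6, 0.2, 1.0), 12)  # more pairs than frames
  st <- pair_store(v, pairs = data.frame(i = 1:12, j = 2:13))
  pc_cov <- pca_contacts(st, force_route = "covariance")
  pc_gram <- pca_contacts(st, force_route = "gram")
  rank <- sum(pc_cov$eigenvalues > 1e-12)
  expect_equal(pc_gram$eigenvalues[1:rank], pc_cov$eigenvalues[1:rank],
               tolerance = 1e-10)
  expect_equal(pc_gram$projections[, 1:rank], pc_cov$projections[, 1:rank],
               tolerance = 1e-8)
  expect_equal(pc_gram$loadings[, 1:rank], pc_cov$loadings[, 1:rank],
               tolerance = 1e-8)
})

test_that("PC1 separates the two states and a state-feature PCA also works", {
  fx <- make_fixture("two_state", n_frames = 100, noise_sigma = 0.01, seed = 5)
  topo <- load_topology(fx$topology_path)
  sel <- select_atoms(topo)
  st <- build_pair_store(read_frames(fx$trajectory_path, topo), sel)
  pc <- pca_contacts(st, n_components = 2)
  states <- fx$ground_truth$states
  p1 <- pc$projections[, 1]
  expect_true(max(p1[states == 0]) < min(p1[states == 1]) ||
              max(p1[states == 1]) < min(p1[states == 0]))
  expect_gte(pc$eigenvalues[1] / sum(pc$eigenvalues), 0.9)
  pc_state <- pca_contacts(st, n_components = 1, features = "state")
  expect_s3_class(pc_state, "pca_contacts")
})

test_that("residue clustering recovers scripted blocks from encounter features", {
  # two rigid 4-residue blocks, fully connected internally and in permanent
  # contact; every cross-block contact breaks at frame 10 as the blocks part
  blockA <- 1:4; blockB <- 5:8
  within <- rbind(t(combn(blockA, 2)), t(combn(blockB, 2)))
  across <- as.matrix(expand.grid(i = blockA, j = blockB))
  pairs <- data.frame(i = c(within[, 1], across[, 1]),
                      j = c(within[, 2], across[, 2]))
  n_f <- 30L
  vals <- rbind(
    matrix(0.4, nrow(within), n_f),
    t(sapply(seq_len(nrow(across)), function(p)
      c(rep(0.4, 11), rep(1.0, n_f - 11))))  # on through frame 10 (0-based)
  )
  st <- pair_store(vals, pairs = pairs)
  agg <- aggregate_map(st)
  L <- map_matrix(agg, "last_ps")
  diag(L) <- 0
  rc <- cluster_residues(L, k = 2)
  expect_equal(rc$labels[blockA], rep(rc$labels[1], 4))
  expect_equal(rc$labels[blockB], rep(rc$labels[5], 4))
  expect_true(rc$labels[1] != rc$labels[5])
})

test_that("residue clustering handles k = 1, inert residues and degeneracy", {
  feats <- rbind(c(1, 0), c(1.1, 0), c(5, 5), c(5.1, 5))
  rc <- cluster_residues(feats, k = 1)
  expect_equal(rc$labels, rep(0L, 4))
  rc2 <- cluster_residues(feats, k = 2, inert = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(rc2$labels[4], -1L)
  expect_error(cluster_residues(matrix(1, 4, 2), k = 2), "degenerate")
  # permuting residue order permutes labels consistently
  perm <- c(3, 1, 4, 2)
  rc3 <- cluster_residues(feats[perm, ], k = 2)
  base <- cluster_residues(feats, k = 2)
  agree <- outer(rc3$labels, rc3$labels, "==") ==
    outer(base$labels[perm], base$labels[perm], "==")
  expect_true(all(agree))
})
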