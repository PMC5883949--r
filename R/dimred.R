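#' Inter-frame contact RMSD matrix
#'
#' The fit-free alternative to coordinate RMSD: for frames a and b,
#' `D[a, b] = sqrt(mean over live pairs of (d_p(a) - d_p(b))^2)` on the
#' clamped distances. D is symmetric with a zero diagonal and, being the
#' Euclidean norm of pair-vector differences scaled by `1/sqrt(P)`,
#' satisfies the triangle inequality.
#'
#' @param store a `"pair_store"` with >= 2 frames and >= 1 live pair.
#' @return `"frame_dist"` object: list with `D` (n_frames x n_frames, nm)
#'   and `times`.
#' @export
interframe_rmsd <- function(store) {
  stopifnot(inherits(store, "pair_store"))
  if (nrow(store$pairs) < 1L) stop("no live pairs: inter-frame RMSD undefined")
  if (store$n_frames < 2L) stop("need at least 2 frames")
  P <- nrow(store$values)
  D <- as.matrix(stats::dist(t(store$values))) / sqrt(P)
  dimnames(D) <- NULL
  structure(list(D = D, times = store$times), class = "frame_dist")
}

#' Hierarchical clustering of trajectory frames
#'
#' Agglomerative clustering on an inter-frame contact RMSD matrix, cut
#' either to `k` clusters or at merge height `h`. Labels are 0-based and
#' renumbered by first frame occurrence. Each cluster's medoid is the
#' member frame minimizing the total distance to all other members (ties
#' broken by the lowest frame index).
#'
#' @param fd a `"frame_dist"` object (or plain symmetric matrix).
#' @param k number of clusters (1..n_frames), or `NULL` to cut at `h`.
#' @param h merge height (nm) used when `k` is `NULL`.
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return `"cluster_result"`: list with `labels` (0-based per frame),
#'   `medoid` (1-based frame index per cluster, in label order),
#'   `distance_to_medoid` (per frame, nm), `merge`, `height` (the
#'   agglomeration record), `k`.
#' @export
cluster_frames <- function(fd, k = NULL, h = NULL,
                           linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  D <- if (inherits(fd, "frame_dist")) fd$D else as.matrix(fd)
  n <- nrow(D)
  if (is.null(k) && is.null(h)) stop("give either k or h")
  if (!is.null(k) && (k < 1L || k > n)) {
    stop("k must lie in 1..", n, " (got ", k, ")")
  }
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  raw <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  labels <- match(raw, unique(raw)) - 1L
  kk <- length(unique(labels))
  medoid <- integer(kk)
  dist_to_med <- numeric(n)
  for (c in seq_len(kk) - 1L) {
    members <- which(labels == c)
    tot <- colSums(D[members, members, drop = FALSE])
    medoid[c + 1L] <- members[which.min(tot)]  # which.min takes first = lowest index
    dist_to_med[members] <- D[medoid[c + 1L], members]
  }
  structure(list(labels = labels, medoid = medoid,
                 distance_to_medoid = dist_to_med,
                 merge = hc$merge, height = hc$height, k = kk,
                 times = if (inherits(fd, "frame_dist")) fd$times else NULL),
            class = "cluster_result")
}

#' Principal component analysis of contact maps
#'
#' Eigendecomposition of the covariance (population convention, divisor N)
#' of the mean-centered per-frame pair-distance vectors; no structural
#' fitting or average coordinates are involved. When there are more live
#' pairs than frames the frames x frames Gram matrix is decomposed instead
#' — the results are identical. Components are ordered by descending
#' eigenvalue; each loading vector's largest-magnitude entry is made
#' positive, fixing the sign deterministically.
#'
#' @param store a `"pair_store"` with >= 2 frames.
#' @param n_components number of components to keep (default: all
#'   `min(n_frames, n_pairs)`).
#' @param features `"distance"` (clamped distances, default) or `"state"`
#'   (0/1 hysteretic contact states).
#' @param force_route `"auto"`, `"covariance"` or `"gram"` — both routes
#'   give identical results; exposed for verification.
#' @return `"pca_contacts"`: list with `eigenvalues` (nm^2, descending,
#'   full spectrum), `loadings` (pairs x components), `projections`
#'   (frames x components), `center` (per-pair mean), `pairs`,
#'   `total_variance`.
#' @export
pca_contacts <- function(store, n_components = NULL,
                         features = c("distance", "state"),
                         force_route = c("auto", "covariance", "gram")) {
  features <- match.arg(features)
  force_route <- match.arg(force_route)
  stopifnot(inherits(store, "pair_store"))
  if (store$n_frames < 2L) stop("need at least 2 frames for PCA")
  X <- if (features == "distance") t(store$values) else
    t(contact_states(store)$states) * 1
  n_f <- nrow(X); n_p <- ncol(X)
  rank_max <- min(n_f, n_p)
  if (is.null(n_components)) n_components <- rank_max
  if (n_components > rank_max) {
    stop("n_components (", n_components, ") exceeds min(n_frames, n_pairs) = ",
         rank_max)
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  route <- if (force_route != "auto") force_route else
    if (n_p > n_f) "gram" else "covariance"
  if (route == "covariance") {
    S <- crossprod(Xc) / n_f
    eg <- eigen(S, symmetric = TRUE)
    lambda <- pmax(eg$values, 0)[seq_len(rank_max)]
    V <- eg$vectors[, seq_len(rank_max), drop = FALSE]
  } else {
    G <- tcrossprod(Xc) / n_f
    eg <- eigen(G, symmetric = TRUE)
    lambda <- pmax(eg$values, 0)[seq_len(rank_max)]
    V <- matrix(0, n_p, rank_max)
    nz <- lambda > max(lambda, 0) * 1e-12
    if (any(nz)) {
      U <- eg$vectors[, seq_len(rank_max), drop = FALSE]
      V[, nz] <- crossprod(Xc, U[, nz, drop = FALSE]) %*%
        diag(1 / sqrt(n_f * lambda[nz]), sum(nz))
    }
  }
  # deterministic sign: largest-|loading| entry positive per component
  for (c in seq_len(ncol(V))) {
    m <- which.max(abs(V[, c]))
    if (length(m) && V[m, c] < 0) V[, c] <- -V[, c]
  }
  proj <- Xc %*% V
  keep <- seq_len(n_components)
  structure(list(
    eigenvalues = lambda,
    loadings = V[, keep, drop = FALSE],
    projections = proj[, keep, drop = FALSE],
    center = ctr, pairs = store$pairs,
    total_variance = sum(diag(crossprod(Xc) / n_f)),
    features = features
  ), class = "pca_contacts")
}

#' Hierarchical clustering of residues
#'
#' Groups residues by the similarity of their per-residue feature vectors —
#' typically rows of the mean-distance matrix, of the (sentinel-filled)
#' last-encounter matrix, or of the contact-count cross-correlation matrix.
#' Useful to delineate domains that unfold or move together. Inert residues
#' (no selected atoms / flagged rows of all-`NA`) receive the reserved
#' label -1.
#'
#' @param features numeric matrix, one row per residue.
#' @param k number of clusters among the non-inert residues.
#' @param inert optional logical vector marking residues to exclude.
#' @param linkage agglomeration method (Euclidean metric).
#' @return `"residue_clusters"`: list with `labels` (0-based, -1 = inert)
#'   and `k`.
#' @export
cluster_residues <- function(features, k,
                             inert = NULL,
                             linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(inert)) inert <- apply(features, 1, function(r) all(is.na(r)))
  act <- which(!inert)
  if (k > length(act)) stop("k exceeds the number of non-inert residues")
  Fa <- features[act, , drop = FALSE]
  Fa[is.na(Fa)] <- 0
  d <- stats::dist(Fa)
  if (k > 1L && max(d) == 0) {
    stop("degenerate input: all residue feature rows identical, cannot form ",
         k, " clusters")
  }
  raw <- stats::cutree(stats::hclust(d, method = linkage), k = k)
  labels <- rep(-1L, n)
  labels[act] <- match(raw, unique(raw)) - 1L
  structure(list(labels = labels, k = k), class = "residue_clusters")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("frame clustering:", length(x$labels), "frames in", x$k,
      "clusters; medoid frames:", paste(x$medoid, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pca_contacts <- function(x, ...) {
  frac <- x$eigenvalues / max(sum(x$eigenvalues), .Machine$double.eps)
  cat("contact-map PCA (", x$features, "features ):",
      ncol(x$loadings), "components;",
      sprintf("PC1 explains %.1f%% of variance", 100 * frac[1]), "\n")
  invisible(x)
}
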