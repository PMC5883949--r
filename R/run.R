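#' Run a full contact analysis from a configuration
#'
#' The single-entry driver behind the command line: loads topology and
#' trajectory, builds the live-pair store, and writes every requested
#' artifact into the output directory. Always written (with
#' `aggregates true`): the mean/sd/min distance maps, contact-fraction
#' map, first/last-encounter maps and the per-pair table. Optional
#' analyses add the time-correlation map, observable-correlation map,
#' contact-count cross-correlation, frame clustering (dendrogram + cluster
#' timeline), residue clusters, and PCA tables. All text outputs are
#' deterministic: re-running a configuration reproduces them byte for
#' byte.
#'
#' @param config a `"run_config"` from [parse_input()], or a path to a
#'   configuration file.
#' @param output_dir overrides the configured output directory.
#' @param images overrides the configured image toggle.
#' @param log_level `"info"` or `"quiet"`.
#' @return invisibly, a list with the computed objects (`store` or
#'   `aggregate`, `timeline`, and any optional results) and the vector of
#'   files written.
#' @export
run_analysis <- function(config, output_dir = NULL, images = NULL,
                         log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.character(config)) config <- parse_input(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- if (!is.null(output_dir)) output_dir else config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(images)) config$images <- images

  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (log_level == "info") message(line)
  }
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  ver <- as.character(utils::packageVersion("contactdyn"))
  say("contactdyn version ", ver)
  say("configuration:")
  for (l in serialize_config(config)) say("  ", l)

  topo <- load_topology(config$topology, config$topology_format)
  say("topology: ", nrow(topo$atoms), " atoms, ", topo$n_residues, " residues")
  restrict <- if (!is.na(config$restrict_file)) {
    read_restriction(config$restrict_file)
  }
  sel <- select_atoms(topo, config$atom_class, restrict = restrict)
  say("atom class '", config$atom_class, "': ",
      sum(lengths(sel$atoms)), " atoms selected, ",
      sum(sel$inert), " inert residue(s)")
  traj <- read_frames(config$trajectory, topo, config$trajectory_format,
                      begin = config$begin, end = config$end,
                      stride = config$stride, dt = config$dt)
  say("frames: ", traj$n_frames, " in analysis window")
  cutoffs <- cutoff_scheme(config$r_cut, config$r_inter, config$r_inter_high)

  res <- list(config = config)
  if (config$mode == "economy") {
    agg <- build_pair_store(traj, sel, cutoffs, config$min_seq_separation,
                            mode = "economy")
    say("live pairs: ", nrow(agg), " (economy mode)")
    res$aggregate <- agg
    write_aggregate_outputs(agg, outdir, config, emit)
  } else {
    store <- build_pair_store(traj, sel, cutoffs, config$min_seq_separation)
    say("live pairs: ", nrow(store$pairs))
    timeline <- contact_states(store)
    agg <- aggregate_map(store, timeline)
    res$store <- store
    res$timeline <- timeline
    res$aggregate <- agg
    if (config$aggregates) write_aggregate_outputs(agg, outdir, config, emit)

    if (config$time_correlation) {
      tc <- time_correlation(store)
      res$time_correlation <- tc
      M <- corr_matrix(tc)
      emit(write_matrix(M, file.path(outdir, "time_correlation.dat"),
                        "pearson r of pair distance vs time",
                        c(diagonal = "nan", undefined = "nan")))
      if (config$images) {
        emit(render_map_png(M, file.path(outdir, "time_correlation.png"),
                            "divergent", midpoint = 0,
                            main = "distance-time correlation"))
      }
      say("time correlation: ", sum(!is.na(tc$r)), " defined pairs")
    }
    if (!is.na(config$observable)) {
      obs <- read_observable(config$observable)
      oc <- observable_correlation(store, obs,
                                   nearest = config$observable_nearest)
      res$observable_correlation <- oc
      M <- corr_matrix(oc)
      emit(write_matrix(M, file.path(outdir, "observable_correlation.dat"),
                        "pearson r of pair distance vs observable",
                        c(diagonal = "nan", undefined = "nan")))
      if (config$images) {
        emit(render_map_png(M, file.path(outdir, "observable_correlation.png"),
                            "divergent", midpoint = 0,
                            main = "distance-observable correlation"))
      }
      say("observable correlation against ", config$observable)
    }
    if (config$cross_correlation) {
      cc <- cross_correlation(contact_counts(timeline))
      res$cross_correlation <- cc
      emit(write_matrix(cc$C, file.path(outdir, "cross_correlation.dat"),
                        "pearson r of residue contact counts",
                        c(diagonal = "nan", constant_count = "nan")))
      if (config$images) {
        emit(render_map_png(cc$C, file.path(outdir, "cross_correlation.png"),
                            "divergent", midpoint = 0,
                            main = "contact-count cross-correlation"))
      }
      say("cross-correlation over ", nrow(cc$C), " residues")
    }
    if (config$cluster_frames) {
      fd <- interframe_rmsd(store)
      cl <- cluster_frames(fd, k = config$cluster_k,
                           linkage = config$cluster_linkage)
      res$frame_dist <- fd
      res$frame_clusters <- cl
      emit(write_matrix(fd$D, file.path(outdir, "interframe_rmsd.dat"),
                        "inter-frame contact RMSD (nm)"))
      emit(write_cluster_tables(cl, outdir))
      if (config$images) {
        emit(render_map_png(fd$D, file.path(outdir, "interframe_rmsd.png"),
                            "sequential", main = "inter-frame contact RMSD"))
      }
      say("frame clustering: k = ", cl$k, ", medoids at frames ",
          paste(cl$medoid, collapse = ", "))
    }
    if (config$cluster_residues) {
      feats <- switch(config$residue_feature,
        mean = map_matrix(agg, "mean"),
        last_encounter = map_matrix(agg, "last_ps"),
        crosscor = cross_correlation(contact_counts(timeline))$C)
      diag(feats) <- 0
      rc <- cluster_residues(feats, k = config$residue_k, inert = sel$inert)
      res$residue_clusters <- rc
      tab <- data.frame(residue = seq_along(rc$labels), label = rc$labels)
      p <- file.path(outdir, "residue_clusters.dat")
      utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
      say("residue clustering on '", config$residue_feature, "' features")
    }
    if (config$pca) {
      pc <- pca_contacts(store, n_components = config$n_components)
      res$pca <- pc
      emit(write_pca_tables(pc, outdir, store$n_residues))
      say("PCA: PC1 explains ",
          sprintf("%.1f%%", 100 * pc$eigenvalues[1] /
                    max(sum(pc$eigenvalues), .Machine$double.eps)),
          " of variance")
    }
    if (config$per_frame_images && config$images) {
      for (f in seq_len(store$n_frames)) {
        M <- frame_matrix(store, f)
        emit(render_map_png(M, file.path(outdir,
                                         sprintf("frame_%05d.png", f - 1L)),
                            "sequential", zlim = c(0, store$cutoffs$r_cut),
                            main = sprintf("t = %g ps", store$times[f])))
      }
      if (config$video) {
        ok <- encode_video(file.path(outdir, "frame_%05d.png"),
                           file.path(outdir, "contacts.mp4"))
        if (ok) emit(file.path(outdir, "contacts.mp4"))
      }
    }
  }
  say("wrote ", length(written), " file(s): ",
      paste(sort(basename(written)), collapse = ", "))
  writeLines(log_lines, file.path(outdir, "run.log"))
  res$files <- c(written, file.path(outdir, "run.log"))
  invisible(res)
}

# full square matrix of one frame's clamped distances
frame_matrix <- function(store, f) {
  n <- store$n_residues
  M <- matrix(store$cutoffs$r_cut, n, n)
  idx <- cbind(store$pairs$i, store$pairs$j)
  M[idx] <- store$values[, f]
  M[idx[, 2:1, drop = FALSE]] <- store$values[, f]
  diag(M) <- NA_real_
  M
}

corr_matrix <- function(pc) {
  n <- attr(pc, "n_residues")
  M <- matrix(NA_real_, n, n)
  idx <- cbind(pc$i, pc$j)
  M[idx] <- pc$r
  M[idx[, 2:1, drop = FALSE]] <- pc$r
  M
}

write_aggregate_outputs <- function(agg, outdir, config, emit) {
  cutoffs <- attr(agg, "cutoffs")
  maps <- list(
    mean_distance = list(stat = "mean", sem = "mean clamped distance (nm)",
                         sent = c(diagonal = "nan",
                                  never_live = sprintf("%g", cutoffs$r_cut))),
    std_distance = list(stat = "sd", sem = "distance standard deviation (nm)",
                        sent = c(diagonal = "nan", never_live = "0")),
    min_distance = list(stat = "min", sem = "minimum distance (nm)",
                        sent = c(diagonal = "nan",
                                 never_live = sprintf("%g", cutoffs$r_cut))),
    contact_fraction = list(stat = "fraction", sem = "hysteretic contact fraction",
                            sent = c(diagonal = "nan", never_live = "0")),
    first_encounter = list(stat = "first_ps", sem = "first encounter time (ps)",
                           sent = c(diagonal = "nan", never_on = "-1")),
    last_encounter = list(stat = "last_ps", sem = "last encounter time (ps)",
                          sent = c(diagonal = "nan", never_on = "-1",
                                   persistent = "-2"))
  )
  for (nm in names(maps)) {
    m <- maps[[nm]]
    M <- map_matrix(agg, m$stat)
    emit(write_matrix(M, file.path(outdir, paste0(nm, ".dat")), m$sem, m$sent))
    if (config$images) {
      emit(render_map_png(M, file.path(outdir, paste0(nm, ".png")),
                          "sequential", main = gsub("_", " ", nm)))
    }
  }
  emit(write_pair_table(agg, file.path(outdir, "pair_stats.tsv")))
}

write_cluster_tables <- function(cl, outdir) {
  dendro <- data.frame(child_a = cl$merge[, 1], child_b = cl$merge[, 2],
                       height_nm = sprintf("%.6g", cl$height))
  p1 <- file.path(outdir, "dendrogram.dat")
  utils::write.table(dendro, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  tl <- data.frame(frame = seq_along(cl$labels) - 1L,
                   time_ps = if (!is.null(cl$times)) cl$times else NA,
                   label = cl$labels,
                   distance_to_medoid = sprintf("%.6g", cl$distance_to_medoid))
  p2 <- file.path(outdir, "cluster_timeline.dat")
  utils::write.table(tl, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  c(p1, p2)
}

write_pca_tables <- function(pc, outdir, n_residues) {
  p1 <- file.path(outdir, "pca_eigenvalues.dat")
  utils::write.table(
    data.frame(component = seq_along(pc$eigenvalues),
               eigenvalue_nm2 = sprintf("%.6g", pc$eigenvalues)),
    p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(outdir, "pca_projections.dat")
  proj <- as.data.frame(pc$projections)
  names(proj) <- paste0("pc", seq_len(ncol(proj)))
  proj[] <- lapply(proj, function(x) sprintf("%.6g", x))
  utils::write.table(cbind(frame = seq_len(nrow(proj)) - 1L, proj),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(p1, p2)
  for (c in seq_len(ncol(pc$loadings))) {
    M <- matrix(0, n_residues, n_residues)
    idx <- cbind(pc$pairs$i, pc$pairs$j)
    M[idx] <- pc$loadings[, c]
    M[idx[, 2:1, drop = FALSE]] <- pc$loadings[, c]
    diag(M) <- NA_real_
    p <- file.path(outdir, sprintf("pca_loadings_pc%d.dat", c))
    write_matrix(M, p, sprintf("PCA loadings, component %d", c),
                 c(diagonal = "nan", never_live = "0"))
    out <- c(out, p)
  }
  out
}
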