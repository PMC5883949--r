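# keyword table: name, type, default (NULL = required/absent)
config_keywords <- function() {
  list(
    topology = list(type = "path", default = NULL, required = TRUE),
    trajectory = list(type = "path", default = NULL, required = TRUE),
    trajectory_format = list(type = "choice", default = "auto",
                             choices = c("auto", "plain", "pdb", "dcd")),
    topology_format = list(type = "choice", default = "auto",
                           choices = c("auto", "pdb", "gro")),
    atom_class = list(type = "choice", default = "heavy",
                      choices = c("heavy", "c_alpha", "backbone",
                                  "side_chain", "all")),
    r_cut = list(type = "num", default = 1.0),
    r_inter = list(type = "num", default = 0.5),
    r_inter_high = list(type = "num", default = NA_real_),  # defaults to r_inter
    begin = list(type = "num", default = -Inf),
    end = list(type = "num", default = Inf),
    stride = list(type = "int", default = 1L),
    dt = list(type = "num", default = 1.0),
    mode = list(type = "choice", default = "full",
                choices = c("full", "economy")),
    min_seq_separation = list(type = "int", default = 1L),
    restrict_file = list(type = "path", default = NA_character_),
    observable = list(type = "path", default = NA_character_),
    observable_nearest = list(type = "bool", default = FALSE),
    aggregates = list(type = "bool", default = TRUE),
    time_correlation = list(type = "bool", default = FALSE),
    cross_correlation = list(type = "bool", default = FALSE),
    cluster_frames = list(type = "bool", default = FALSE),
    cluster_k = list(type = "int", default = 2L),
    cluster_linkage = list(type = "choice", default = "average",
                           choices = c("average", "single", "complete")),
    cluster_residues = list(type = "bool", default = FALSE),
    residue_feature = list(type = "choice", default = "mean",
                           choices = c("mean", "last_encounter", "crosscor")),
    residue_k = list(type = "int", default = 2L),
    pca = list(type = "bool", default = FALSE),
    n_components = list(type = "int", default = 2L),
    output_dir = list(type = "path", default = "."),
    images = list(type = "bool", default = TRUE),
    per_frame_images = list(type = "bool", default = FALSE),
    video = list(type = "bool", default = FALSE)
  )
}

#' Parse a run-configuration file
#'
#' The whole analysis is driven by a single keyword file: one
#' `keyword value` pair per line, `#` comments and blank lines ignored.
#' Unknown keywords are rejected with the offending line number; defaults
#' are applied for everything omitted (`r_cut` 1.0, `r_inter` 0.5,
#' `r_inter_high` = `r_inter`, `atom_class` heavy, `stride` 1, `mode`
#' full) and every resolved value is echoed to the run log. Cutoff
#' ordering (`r_inter <= r_inter_high <= r_cut`) is enforced at parse
#' time, as is the rule that economy mode supports only aggregate maps.
#'
#' @param path configuration file.
#' @return `"run_config"`: named list of resolved settings.
#' @seealso [serialize_config()], [run_analysis()]
#' @export
parse_input <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  kw <- config_keywords()
  cfg <- lapply(kw, function(x) x$default)
  lines <- readLines(path, warn = FALSE)
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    m <- regmatches(raw, regexec("^(\\S+)\\s+(.*)$", raw))[[1]]
    if (length(m) != 3L) stop("malformed line ", ln, " in ", path, ": '",
                              lines[ln], "'")
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(kw)) {
      stop("unknown keyword '", key, "' at line ", ln, " of ", path)
    }
    spec <- kw[[key]]
    cfg[[key]] <- switch(spec$type,
      path = val,
      num = {
        v <- suppressWarnings(as.numeric(val))
        if (is.na(v) && !identical(tolower(val), "nan")) {
          stop("keyword '", key, "' at line ", ln, " needs a number, got '",
               val, "'")
        }
        v
      },
      int = {
        v <- suppressWarnings(as.integer(val))
        if (is.na(v)) stop("keyword '", key, "' at line ", ln,
                           " needs an integer, got '", val, "'")
        v
      },
      bool = {
        lv <- tolower(val)
        if (!lv %in% c("true", "false", "yes", "no", "on", "off")) {
          stop("keyword '", key, "' at line ", ln,
               " needs true/false, got '", val, "'")
        }
        lv %in% c("true", "yes", "on")
      },
      choice = {
        if (!val %in% spec$choices) {
          stop("keyword '", key, "' at line ", ln, " must be one of ",
               paste(spec$choices, collapse = "/"), ", got '", val, "'")
        }
        val
      })
  }
  for (key in names(kw)) {
    if (isTRUE(kw[[key]]$required) && is.null(cfg[[key]])) {
      stop("required keyword '", key, "' missing in ", path)
    }
  }
  if (is.na(cfg$r_inter_high)) cfg$r_inter_high <- cfg$r_inter
  if (!(cfg$r_inter > 0 && cfg$r_inter <= cfg$r_inter_high &&
        cfg$r_inter_high <= cfg$r_cut)) {
    stop("cutoff ordering violated: need 0 < r_inter <= r_inter_high <= ",
         "r_cut (got ", cfg$r_inter, ", ", cfg$r_inter_high, ", ",
         cfg$r_cut, ")")
  }
  if (cfg$stride < 1L) stop("stride must be >= 1")
  if (cfg$mode == "economy") {
    blocked <- c("time_correlation", "cross_correlation", "cluster_frames",
                 "cluster_residues", "pca")
    bad <- blocked[vapply(blocked, function(b) isTRUE(cfg[[b]]), logical(1))]
    if (length(bad) || !is.na(cfg$observable)) {
      stop("economy mode stores no per-frame values; it supports only ",
           "aggregates (requested: ",
           paste(c(bad, if (!is.na(cfg$observable)) "observable"),
                 collapse = ", "), ")")
    }
  }
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration
#'
#' Writes the fully resolved keyword file; `parse_input()` on the result
#' reproduces the configuration exactly.
#'
#' @param config a `"run_config"`.
#' @param path output file (or `NULL` to return the lines).
#' @return the lines, invisibly when written.
#' @export
serialize_config <- function(config, path = NULL) {
  fmt <- function(key, v) {
    if (is.logical(v)) v <- if (v) "true" else "false"
    paste(key, v)
  }
  keep <- !vapply(config, function(v) length(v) != 1L || is.na(v), logical(1))
  lines <- mapply(fmt, names(config)[keep], config[keep], USE.NAMES = FALSE)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration:\n")
  cat(paste(" ", serialize_config(x)), sep = "\n")
  invisible(x)
}
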