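# color conventions: sequential palette for distances/times, divergent
# palette (white at the null value) for correlations and differences
sequential_palette <- function(n = 64L) {
  grDevices::colorRampPalette(c("#000000", "#16336B", "#4B7A4C",
                                "#C2804C", "#F0C3E7", "#FFFFFF"))(n)
}

divergent_palette <- function(n = 11L) {
  grDevices::colorRampPalette(c("#7F3B08", "#E08214", "#FDB863",
                                "#FFFFFF", "#B2ABD2", "#8073AC",
                                "#2D004B"))(n)
}

#' Render a residue matrix as a PNG heat map
#'
#' Sequential data (distances, times, fractions) use a dark-to-light
#' sequential ramp; divergent data (correlations, differential maps) use an
#' orange-white-purple ramp whose midpoint is anchored exactly at the null
#' value, so "no change" is always white.
#'
#' @param M square matrix (`NA` cells drawn blank).
#' @param path output PNG.
#' @param type `"sequential"` or `"divergent"`.
#' @param midpoint null value anchored to the palette center (divergent).
#' @param main plot title.
#' @param zlim optional value range.
#' @return `path`, invisibly.
#' @export
render_map_png <- function(M, path, type = c("sequential", "divergent"),
                           midpoint = 0, main = "", zlim = NULL) {
  type <- match.arg(type)
  n <- nrow(M)
  grDevices::png(path, width = 640, height = 600)
  on.exit(grDevices::dev.off())
  if (type == "divergent") {
    half <- max(abs(range(M - midpoint, na.rm = TRUE, finite = TRUE)), 1e-12)
    zlim <- midpoint + c(-half, half)  # symmetric => midpoint at center color
    pal <- divergent_palette(255L)
  } else {
    if (is.null(zlim)) zlim <- range(M, na.rm = TRUE, finite = TRUE)
    if (diff(zlim) == 0) zlim <- zlim + c(-1e-12, 1e-12)
    pal <- sequential_palette(255L)
  }
  graphics::image(seq_len(n), seq_len(n), t(M), zlim = zlim, col = pal,
                  xlab = "residue j", ylab = "residue i", main = main,
                  useRaster = TRUE)
  invisible(path)
}

#' Map a value to its rendered color
#'
#' The color-lookup used by [render_map_png()], exposed so the palette
#' conventions are testable: under `type = "divergent"` the midpoint value
#' maps to the central palette entry (white).
#'
#' @param value numeric value(s).
#' @param lo,hi data range used for the plot.
#' @param type `"sequential"` or `"divergent"`.
#' @param midpoint divergent null value.
#' @return hex color(s).
#' @export
map_color <- function(value, lo, hi, type = c("sequential", "divergent"),
                      midpoint = 0) {
  type <- match.arg(type)
  if (type == "divergent") {
    half <- max(abs(c(lo, hi) - midpoint))
    lo <- midpoint - half; hi <- midpoint + half
    pal <- divergent_palette(255L)
  } else {
    pal <- sequential_palette(255L)
  }
  idx <- pmin(pmax(round((value - lo) / (hi - lo) * 254) + 1, 1), 255)
  pal[idx]
}

#' Encode per-frame images into a video
#'
#' Thin wrapper over an external encoder (`ffmpeg` or `avconv`): probes the
#' PATH at run time and, if no encoder is found, logs a warning and skips —
#' never a failure, since the video is presentation-only.
#'
#' @param frame_glob printf-style pattern of the frame PNGs
#'   (e.g. `"frame_%05d.png"`).
#' @param out output MP4 path.
#' @param fps frames per second.
#' @return `TRUE` if a video was written, `FALSE` if skipped.
#' @export
encode_video <- function(frame_glob, out, fps = 10) {
  enc <- Sys.which(c("ffmpeg", "avconv"))
  enc <- enc[nzchar(enc)][1]
  if (is.na(enc)) {
    warning("no video encoder (ffmpeg/avconv) on PATH; skipping video")
    return(invisible(FALSE))
  }
  status <- system2(enc, c("-y", "-loglevel", "error", "-framerate", fps,
                           "-i", shQuote(frame_glob), "-pix_fmt", "yuv420p",
                           shQuote(out)))
  if (status != 0) {
    warning("video encoder exited with status ", status, "; skipping video")
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
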