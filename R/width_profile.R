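# The width profile (kymograph): vessel width at every pixel row along the
# vessel, in every frame. Width is the COUNT of vessel pixels in a row, not
# the outer-edge span; the small-component filter has already removed stray
# specks that would corrupt counts, and the two definitions differ only for
# vessels with interior holes. A row is flagged missing (NA) when any of its
# vessel pixels falls inside the saturation-exclusion zone — glare makes the
# vessel look narrower there, so the measurement is dropped rather than
# recorded wrong. An empty row is width 0, not missing.

#' Width profile container
#'
#' @param widths numeric matrix, frames x positions; \code{NA} marks
#'   excluded (not measurable) cells.
#' @param fps frames per second (\code{NA} for single-image mode).
#' @param mm_per_px calibration, or \code{NA} if uncalibrated.
#' @return Object of class \code{width_profile}.
#' @export
width_profile <- function(widths, fps = NA_real_, mm_per_px = NA_real_) {
  widths <- as.matrix(widths)
  if (any(widths < 0, na.rm = TRUE)) stop("widths must be >= 0")
  structure(list(widths = widths, fps = as.numeric(fps),
                 mm_per_px = as.numeric(mm_per_px),
                 n_frames = nrow(widths), n_positions = ncol(widths)),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat("<width_profile> ", x$n_frames, " frame(s) x ", x$n_positions,
      " position(s); ", sum(is.na(x$widths)), " excluded cell(s)\n", sep = "")
  cat("  fps = ", format(x$fps), ", mm_per_px = ", format(x$mm_per_px),
      "\n", sep = "")
  invisible(x)
}

#' Vessel width in each pixel row of one segmented frame
#'
#' @param seg a \code{segmented_frame} from a vertically-oriented ROI clip.
#' @return List with \code{width} (vessel pixel count per row) and
#'   \code{missing} (logical; \code{TRUE} where a vessel pixel in the row
#'   intersects the exclusion zone).
#' @export
row_widths <- function(seg) {
  width <- rowSums(seg$vessel_mask)
  missing <- rowSums(seg$vessel_mask & seg$exclusion_mask) > 0
  list(width = as.numeric(width), missing = missing)
}

#' Build the width profile from segmented frames
#'
#' @param segs list of \code{segmented_frame} (see [segment_video]).
#' @param fps frames per second.
#' @param calib a [calibration], bare mm-per-px scalar, or \code{NULL}.
#' @return A [width_profile]; excluded cells are \code{NA}.
#' @export
build_profile <- function(segs, fps = NA_real_, calib = NULL) {
  if (length(segs) < 1L) stop("need at least one segmented frame")
  d <- dim(segs[[1L]]$vessel_mask)
  widths <- matrix(NA_real_, length(segs), d[1L])
  for (i in seq_along(segs)) {
    if (!identical(dim(segs[[i]]$vessel_mask), d))
      stop("frame ", i, " has inconsistent dimensions")
    rw <- row_widths(segs[[i]])
    w <- rw$width
    w[rw$missing] <- NA_real_
    widths[i, ] <- w
  }
  width_profile(widths, fps = fps, mm_per_px = as_mm_per_px(calib))
}

#' Mean vessel width over time
#'
#' Per frame, the mean width over non-missing positions in \code{y_range}.
#' A frame whose positions are more than half missing is itself missing.
#'
#' @param profile a [width_profile].
#' @param y_range optional integer interval \code{c(first, last)} of
#'   positions (1-based, inclusive); default all positions.
#' @return Numeric vector, one mean width (px) per frame, \code{NA} for
#'   majority-missing frames.
#' @export
mean_width_series <- function(profile, y_range = NULL) {
  stopifnot(inherits(profile, "width_profile"))
  if (is.null(y_range)) y_range <- c(1L, profile$n_positions)
  if (y_range[1L] < 1L || y_range[2L] > profile$n_positions ||
      y_range[1L] > y_range[2L])
    stop("y_range [", y_range[1L], ", ", y_range[2L],
         "] outside profile positions 1..", profile$n_positions)
  sub <- profile$widths[, y_range[1L]:y_range[2L], drop = FALSE]
  n_missing <- rowSums(is.na(sub))
  out <- rowMeans(sub, na.rm = TRUE)
  out[n_missing > ncol(sub) / 2] <- NA_real_
  out[is.nan(out)] <- NA_real_
  out
}

#' Maximum diameter change (peak minus nadir) along the vessel
#'
#' For each position, the range of its width over all frames where it was
#' measurable, in physical units when calibrated (px otherwise).
#'
#' @param profile a [width_profile] with at least 2 frames.
#' @return Numeric vector, one peak-minus-nadir value per position
#'   (\code{NA} where the position was never measurable); in mm if
#'   \code{mm_per_px} is set, else px (attribute \code{"units"} says which).
#' @export
max_change_profile <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  if (profile$n_frames < 2L) stop("need >= 2 frames for a change profile")
  rng <- apply(profile$widths, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(NA_real_)
    max(col) - min(col)
  })
  if (!is.na(profile$mm_per_px)) {
    structure(rng * profile$mm_per_px, units = "mm")
  } else {
    structure(rng, units = "px")
  }
}

# ---- CSV round-trip ---------------------------------------------------------

#' Write the width profile as a long-format CSV
#'
#' Columns \code{frame_index}, \code{position_index} (both 0-based, position
#' 0 at the top of the ROI), \code{width_px} (empty for excluded cells) and
#' \code{excluded_flag}. Frame rate and calibration are carried in
#' \code{#}-prefixed header lines so the round-trip through
#' [read_width_csv] is lossless.
#'
#' @param profile a [width_profile].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_width_csv <- function(profile, path) {
  stopifnot(inherits(profile, "width_profile"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# fps: ", format(profile$fps, digits = 17)),
               paste0("# mm_per_px: ", format(profile$mm_per_px, digits = 17))),
             con)
  idx <- expand.grid(position_index = seq_len(profile$n_positions) - 1L,
                     frame_index = seq_len(profile$n_frames) - 1L)
  w <- as.vector(t(profile$widths))
  df <- data.frame(frame_index = idx$frame_index,
                   position_index = idx$position_index,
                   width_px = w,
                   excluded_flag = is.na(w))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a width-profile CSV written by [write_width_csv]
#'
#' @param path CSV path.
#' @return A [width_profile].
#' @export
read_width_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  num <- function(line) as.numeric(sub("^# [a-z_]+: ", "", line))
  df <- utils::read.csv(path, comment.char = "#")
  n_frames <- max(df$frame_index) + 1L
  n_pos <- max(df$position_index) + 1L
  widths <- matrix(NA_real_, n_frames, n_pos)
  widths[cbind(df$frame_index + 1L, df$position_index + 1L)] <- df$width_px
  width_profile(widths, fps = num(hdr[1L]), mm_per_px = num(hdr[2L]))
}

# ---- heatmap ----------------------------------------------------------------

#' Kymograph heatmap
#'
#' Time on x, position along the vessel on y (position 0 at the top),
#' colour = vessel width (mm when calibrated). Excluded cells are white.
#' \code{plot()} on a [width_profile] draws the same figure on the current
#' device.
#'
#' @param profile a [width_profile].
#' @param path output PNG path.
#' @param width,height device size in px.
#' @return \code{path}, invisibly.
#' @export
render_heatmap <- function(profile, path, width = 900, height = 500) {
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  plot(profile)
  invisible(path)
}

#' @export
plot.width_profile <- function(x, main = "Vessel width", ...) {
  w <- x$widths
  in_mm <- !is.na(x$mm_per_px)
  if (in_mm) w <- w * x$mm_per_px
  tvals <- if (!is.na(x$fps)) (seq_len(x$n_frames) - 1) / x$fps
           else seq_len(x$n_frames) - 1
  cols <- grDevices::hcl.colors(64, "viridis")
  # image() draws y increasing upwards; flip so position 0 is at the top
  graphics::image(tvals, seq_len(x$n_positions) - 1,
                  w[, rev(seq_len(x$n_positions)), drop = FALSE],
                  col = cols, useRaster = TRUE,
                  xlab = if (!is.na(x$fps)) "time (s)" else "frame",
                  ylab = "position from top (px, reversed axis)",
                  main = main, yaxt = "n", ...)
  at <- pretty(c(0, x$n_positions - 1))
  at <- at[at <= x$n_positions - 1]
  graphics::axis(2, at = at, labels = x$n_positions - 1 - at)
  invisible(x)
}
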