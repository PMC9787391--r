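#' Video clip container
#'
#' An ordered sequence of RGB frames with acquisition metadata. Frames are
#' integer arrays of dimension height x width x 3 with intensities in
#' \code{[0, 2^bit_depth - 1]}. A still image is represented as a 1-frame
#' clip with \code{fps = NA} (single-image mode), so spatial operations work
#' unchanged while time-domain operations refuse it.
#'
#' @param frames list of integer arrays, each height x width x 3.
#' @param fps frames per second (> 0), or \code{NA} for a still image.
#' @param bit_depth bits per channel (default 8).
#' @return An object of class \code{video_clip} with fields \code{frames},
#'   \code{fps}, \code{bit_depth}, \code{frame_count}, \code{height},
#'   \code{width}.
#' @export
video_clip <- function(frames, fps = NA_real_, bit_depth = 8L) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("'frames' must be a non-empty list of height x width x 3 arrays")
  d <- dim(frames[[1L]])
  if (length(d) != 3L || d[3L] != 3L)
    stop("each frame must be a height x width x 3 array")
  maxval <- 2^bit_depth - 1
  for (i in seq_along(frames)) {
    fi <- frames[[i]]
    if (!identical(dim(fi), d))
      stop("frame ", i, " dimensions differ from frame 1")
    if (anyNA(fi) || min(fi) < 0 || max(fi) > maxval)
      stop("frame ", i, " has intensities outside [0, ", maxval, "]")
  }
  if (!is.na(fps) && fps <= 0) stop("'fps' must be > 0")
  structure(
    list(frames = frames, fps = as.numeric(fps), bit_depth = as.integer(bit_depth),
         frame_count = length(frames), height = d[1L], width = d[2L]),
    class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  fps <- if (is.na(x$fps)) "NA (still image)" else format(x$fps)
  cat("<video_clip> ", x$frame_count, " frame(s), ",
      x$height, " x ", x$width, " px, ", x$bit_depth, "-bit, fps = ", fps, "\n",
      sep = "")
  invisible(x)
}

#' @rdname video_clip
#' @param x object to test.
#' @export
is_video_clip <- function(x) inherits(x, "video_clip")

# guard used by time-domain entry points
stop_if_still <- function(clip) {
  if (clip$frame_count < 2L || is.na(clip$fps))
    stop("time-domain analysis needs >= 2 frames and a frame rate; ",
         "this input is a still image (single-image mode)")
  invisible(clip)
}

#' Spatial calibration
#'
#' Physical size of one pixel edge. Stored once per analysis; all physical
#' quantities are derived as pixel measures times \code{mm_per_px}.
#'
#' @param mm_per_px millimetres per pixel edge (> 0).
#' @return Object of class \code{calibration}.
#' @export
calibration <- function(mm_per_px) {
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L ||
      !is.finite(mm_per_px) || mm_per_px <= 0)
    stop("'mm_per_px' must be a single positive number")
  structure(list(mm_per_px = as.numeric(mm_per_px)), class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration> ", format(x$mm_per_px), " mm/px (",
      format(x$mm_per_px * 1000), " um/px)\n", sep = "")
  invisible(x)
}

#' Calibrate from two points on a ruler image
#'
#' Given two pixel coordinates spanning a known physical distance (e.g. two
#' graduation marks of a ruler placed in the field of view), returns the
#' calibration \code{distance_mm / euclidean_distance(p1, p2)}.
#'
#' @param p1,p2 numeric length-2 pixel coordinates (row, column); any
#'   consistent convention works since only the euclidean distance is used.
#' @param distance_mm known physical distance between the points, in mm.
#' @return A \code{calibration} object.
#' @examples
#' calibrate_from_points(c(0, 0), c(0, 100), 1)   # 0.01 mm/px
#' @export
calibrate_from_points <- function(p1, p2, distance_mm) {
  if (length(p1) != 2L || length(p2) != 2L)
    stop("'p1' and 'p2' must be length-2 coordinates")
  d <- sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
  if (d == 0) stop("calibration points are coincident")
  if (!is.finite(distance_mm) || distance_mm <= 0)
    stop("'distance_mm' must be > 0")
  calibration(distance_mm / d)
}

#' Convert pixel measures to millimetres
#'
#' @param px numeric vector of pixel measures.
#' @param calib a \code{calibration} object (or a bare mm-per-px scalar).
#' @return numeric vector in mm.
#' @export
px_to_mm <- function(px, calib) {
  px * as_mm_per_px(calib)
}

as_mm_per_px <- function(calib) {
  if (inherits(calib, "calibration")) return(calib$mm_per_px)
  if (is.null(calib)) return(NA_real_)
  if (is.numeric(calib) && length(calib) == 1L) {
    if (is.na(calib)) return(NA_real_)
    if (calib > 0) return(as.numeric(calib))
  }
  stop("'calib' must be a calibration object or a positive scalar")
}
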