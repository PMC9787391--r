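# Region-of-interest definition and extraction.
#
# A ROI is a rotated rectangle isolating one vessel segment; extraction
# resamples the source so the vessel runs vertically in the output. The
# textual form "cx,cy,length,width,angle" (0-based source coordinates,
# cx = column, cy = row, angle in degrees from image vertical) is the exact,
# reproducible record of a selection and is what the reproducibility log
# line carries.

#' Rotated-rectangle region of interest
#'
#' @param cx,cy centre of the rectangle in the source frame, 0-based
#'   (\code{cx} = column, \code{cy} = row).
#' @param length_px extent along the vessel axis, in px (output height).
#' @param width_px extent across the vessel, in px (output width).
#' @param angle_deg rotation of the vessel axis relative to image vertical,
#'   degrees; normalized to (-180, 180]. Positive angles tilt the axis
#'   towards increasing column.
#' @return Object of class \code{roi_spec}.
#' @export
roi_spec <- function(cx, cy, length_px, width_px, angle_deg = 0) {
  if (length_px < 1 || width_px < 1)
    stop("'length_px' and 'width_px' must be >= 1")
  a <- ((angle_deg + 180) %% 360) - 180
  if (a == -180) a <- 180
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy),
                 length_px = as.integer(round(length_px)),
                 width_px = as.integer(round(width_px)),
                 angle_deg = as.numeric(a)),
            class = "roi_spec")
}

#' @export
format.roi_spec <- function(x, ...) {
  num <- function(v) format(v, trim = TRUE, digits = 15)
  paste(num(x$cx), num(x$cy), x$length_px, x$width_px, num(x$angle_deg),
        sep = ",")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat("<roi_spec> ", format(x), "  (cx,cy,length,width,angle)\n", sep = "")
  invisible(x)
}

#' Parse the one-line textual ROI form
#'
#' @param text a string \code{"cx,cy,length,width,angle"}.
#' @return A [roi_spec].
#' @export
parse_roi <- function(text) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(text), ",")[[1L]]))
  if (length(v) != 5L || anyNA(v))
    stop("ROI text must be 'cx,cy,length,width,angle', got: ", text)
  roi_spec(v[1L], v[2L], v[3L], v[4L], v[5L])
}

# sampling grid: source (row, col) 0-based coordinates for each output pixel
roi_grid <- function(roi) {
  th <- roi$angle_deg * pi / 180
  v <- seq_len(roi$length_px) - 1 - (roi$length_px - 1) / 2   # along axis
  u <- seq_len(roi$width_px) - 1 - (roi$width_px - 1) / 2    # across axis
  # vessel axis direction (row, col) = (cos th, sin th); perpendicular (-sin, cos)
  src_r <- outer(v * cos(th), -u * sin(th), `+`) + roi$cy
  src_c <- outer(v * sin(th), u * cos(th), `+`) + roi$cx
  list(r = src_r, c = src_c)
}

roi_corners <- function(roi) {
  g <- roi_grid(roi)
  idx <- rbind(c(1, 1), c(1, roi$width_px),
               c(roi$length_px, 1), c(roi$length_px, roi$width_px))
  cbind(r = g$r[idx], c = g$c[idx])
}

bilinear_sample <- function(plane, r, cl) {
  h <- nrow(plane); w <- ncol(plane)
  r0 <- floor(r); c0 <- floor(cl)
  fr <- r - r0; fc <- cl - c0
  r0 <- pmin(pmax(r0, 0), h - 1); c0 <- pmin(pmax(c0, 0), w - 1)
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  at <- function(rr, cc) plane[cbind(as.vector(rr) + 1L, as.vector(cc) + 1L)]
  val <- at(r0, c0) * (1 - fr) * (1 - fc) + at(r1, c0) * fr * (1 - fc) +
         at(r0, c1) * (1 - fr) * fc       + at(r1, c1) * fr * fc
  matrix(val, nrow = nrow(r))
}

#' Extract a rotated region of interest from every frame
#'
#' Resamples each frame under rotation by \code{-angle_deg} about the ROI
#' centre so the vessel axis is vertical in the output; bilinear
#' interpolation per channel. With \code{angle_deg = 0} this is an exact
#' array crop. The whole rotated rectangle must lie inside the frame.
#'
#' @param clip a [video_clip].
#' @param roi a [roi_spec].
#' @return A [video_clip] of height \code{length_px} and width
#'   \code{width_px}; fps preserved.
#' @export
extract_roi <- function(clip, roi) {
  stopifnot(is_video_clip(clip), inherits(roi, "roi_spec"))
  corners <- roi_corners(roi)
  bad <- corners[, "r"] < 0 | corners[, "r"] > clip$height - 1 |
         corners[, "c"] < 0 | corners[, "c"] > clip$width - 1
  if (any(bad)) {
    msg <- apply(round(corners[bad, , drop = FALSE], 2), 1L,
                 function(p) sprintf("(row %.2f, col %.2f)", p[1], p[2]))
    stop("ROI exceeds frame bounds at corner(s): ", paste(msg, collapse = ", "))
  }
  g <- roi_grid(roi)
  frames <- lapply(clip$frames, function(fr) {
    out <- array(0L, c(roi$length_px, roi$width_px, 3L))
    for (ch in 1:3)
      out[, , ch] <- as.integer(round(bilinear_sample(fr[, , ch], g$r, g$c)))
    out
  })
  video_clip(frames, fps = clip$fps, bit_depth = clip$bit_depth)
}

# footprint of the ROI rectangle in the source frame (logical mask):
# pixel centres whose back-projection into ROI coordinates falls inside
# [-L/2, L/2] x [-W/2, W/2]
roi_footprint <- function(roi, height, width) {
  th <- roi$angle_deg * pi / 180
  rr <- matrix(seq_len(height) - 1, height, width) - roi$cy
  cc <- matrix(seq_len(width) - 1, height, width, byrow = TRUE) - roi$cx
  v <- rr * cos(th) + cc * sin(th)
  u <- -rr * sin(th) + cc * cos(th)
  abs(v) <= roi$length_px / 2 & abs(u) <= roi$width_px / 2
}

#' Render a ROI preview image
#'
#' Writes the frame with the ROI footprint tinted green, the confirmation
#' view shown before a selection is applied to the whole video.
#'
#' @param frame an RGB raster (height x width x 3 integer array) or a
#'   [video_clip] (first frame used).
#' @param roi a [roi_spec].
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
render_roi_preview <- function(frame, roi, path) {
  if (is_video_clip(frame)) frame <- frame$frames[[1L]]
  fp <- roi_footprint(roi, dim(frame)[1L], dim(frame)[2L])
  out <- frame
  for (ch in 1:3) {
    plane <- out[, , ch]
    tint <- c(0L, 255L, 0L)[ch]
    plane[fp] <- as.integer(round(0.5 * plane[fp] + 0.5 * tint))
    out[, , ch] <- plane
  }
  png::writePNG(out / 255, path)
  invisible(path)
}
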