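# Vessel segmentation.
#
# The vessel is filled with blue dye, so it absorbs strongly in the red
# channel: every pixel whose red intensity is strictly below a threshold is
# vessel. The threshold default is the mean of per-frame Otsu splits over a
# few equally spaced frames (one threshold per video; contrast varies across
# preparations, so no absolute default exists). Imaging artifacts are handled
# by removing 8-connected components smaller than a minimum area and by
# excluding everything within a fixed euclidean distance of saturated
# (glare) pixels.

#' Segmentation configuration
#'
#' @param threshold red-channel intensity cutoff; pixels strictly below are
#'   vessel. \code{NULL} until set (e.g. by [auto_threshold] or manually).
#' @param n_sample_frames frames used for the automatic default (default 6).
#' @param min_component_px minimum vessel component area in px; components
#'   strictly smaller are removed (default 10).
#' @param saturation_fraction fraction of the intensity range at or above
#'   which a pixel counts as saturated in all three channels (default 0.99).
#' @param exclusion_radius_px euclidean distance (inclusive) from a saturated
#'   pixel within which measurements are excluded (default 5).
#' @return Object of class \code{threshold_config}.
#' @export
threshold_config <- function(threshold = NULL, n_sample_frames = 6L,
                             min_component_px = 10L,
                             saturation_fraction = 0.99,
                             exclusion_radius_px = 5) {
  if (!is.null(threshold) && (threshold <= 0 || threshold >= 255))
    stop("'threshold' must lie strictly inside the intensity range")
  if (min_component_px < 0) stop("'min_component_px' must be >= 0")
  if (saturation_fraction <= 0 || saturation_fraction > 1)
    stop("'saturation_fraction' must be in (0, 1]")
  if (exclusion_radius_px < 0) stop("'exclusion_radius_px' must be >= 0")
  structure(list(threshold = threshold,
                 n_sample_frames = as.integer(n_sample_frames),
                 min_component_px = as.numeric(min_component_px),
                 saturation_fraction = as.numeric(saturation_fraction),
                 exclusion_radius_px = as.numeric(exclusion_radius_px)),
            class = "threshold_config")
}

#' Otsu threshold of an intensity raster
#'
#' Exhaustive two-class split of the 0..maxval histogram maximizing the
#' between-class variance. When several cutoffs tie (e.g. a bimodal image
#' with an empty gap), the midpoint of the maximizing plateau is returned.
#' The returned value is a cutoff \code{t} such that "vessel = intensity
#' strictly below \code{t}" splits the two classes.
#'
#' @param values integer intensities (vector or matrix).
#' @param maxval top of the intensity range (default 255).
#' @return A single threshold, or \code{NA} if the raster is constant.
#' @export
otsu_threshold <- function(values, maxval = 255L) {
  v <- as.vector(values)
  if (length(unique(v)) < 2L) return(NA_real_)
  counts <- tabulate(v + 1L, nbins = maxval + 1L)
  n <- length(v)
  lev <- 0:maxval
  w0 <- cumsum(counts)                       # pixels with intensity <= lev
  s0 <- cumsum(counts * lev)
  total <- s0[maxval + 1L]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (total - s0) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2             # between-class variance (x n^2)
  bcv[w0 == 0 | w1 == 0] <- -Inf
  best <- which(bcv >= max(bcv) - 1e-9 * abs(max(bcv)))
  # cutoff c means classes {<= c} / {> c}; report threshold t with vessel < t
  (lev[min(best)] + lev[max(best)]) / 2 + 1
}

#' Automatic default threshold from equally spaced frames
#'
#' Applies [otsu_threshold] to the red channel of \code{n_sample_frames}
#' equally spaced frames (first and last included) and returns the mean of
#' the per-frame splits, the video-wide default the user may then override.
#'
#' @param clip a [video_clip].
#' @param n_sample_frames number of frames to sample (default 6).
#' @return Mean threshold (numeric).
#' @export
auto_threshold <- function(clip, n_sample_frames = 6L) {
  stopifnot(is_video_clip(clip), n_sample_frames >= 1L)
  idx <- sample_frame_indices(clip$frame_count, n_sample_frames)
  maxval <- 2^clip$bit_depth - 1
  ts <- vapply(idx, function(i)
    otsu_threshold(clip$frames[[i]][, , 1L], maxval), numeric(1L))
  ts <- ts[!is.na(ts)]
  if (length(ts) == 0L)
    stop("no contrast: every sampled frame has a constant red channel")
  mean(ts)
}

sample_frame_indices <- function(n_total, n_sample) {
  n_sample <- min(n_sample, n_total)
  if (n_sample == 1L) return(1L)
  unique(round(seq(1L, n_total, length.out = n_sample)))
}

# ---- connected components (8-connectivity) ---------------------------------

# frontier-based flood fill; returns an integer label matrix (0 = background)
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  n <- h * w
  offs <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)  # 8-neighbours
  row_of <- function(idx) ((idx - 1L) %% h) + 1L
  todo <- which(mask)
  lab <- 0L
  seen <- !mask
  for (seed in todo) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    frontier <- seed
    labels[seed] <- lab
    while (length(frontier) > 0L) {
      cand <- rep(frontier, each = 8L) + offs
      keep <- cand >= 1L & cand <= n
      # forbid wrap-around across matrix columns: neighbour rows differ by <= 1
      keep <- keep & abs(row_of(pmax(cand, 1L)) -
                         rep(row_of(frontier), each = 8L)) <= 1L
      cand <- unique(cand[keep])
      cand <- cand[mask[cand] & labels[cand] == 0L]
      labels[cand] <- lab
      frontier <- cand
    }
  }
  labels
}

# remove 8-connected components with area strictly below min_px
filter_small_components <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  labels <- label_components(mask)
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= min_px)
  matrix(labels %in% keep, nrow(mask), ncol(mask)) & mask
}

# ---- saturation exclusion ---------------------------------------------------

# all pixels within euclidean distance <= radius (inclusive) of any pixel
# saturated in all three channels
saturation_exclusion <- function(frame, saturation_fraction = 0.99,
                                 radius = 5, maxval = 255L) {
  cutoff <- ceiling(saturation_fraction * maxval)
  sat <- frame[, , 1L] >= cutoff & frame[, , 2L] >= cutoff & frame[, , 3L] >= cutoff
  h <- dim(frame)[1L]; w <- dim(frame)[2L]
  out <- matrix(FALSE, h, w)
  if (!any(sat)) return(out)
  idx <- which(sat, arr.ind = TRUE)
  r <- floor(radius)
  disc <- expand.grid(dr = -r:r, dc = -r:r)
  disc <- disc[disc$dr^2 + disc$dc^2 <= radius^2, ]
  rows <- rep(idx[, 1L], each = nrow(disc)) + disc$dr
  cols <- rep(idx[, 2L], each = nrow(disc)) + disc$dc
  ok <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
  out[cbind(rows[ok], cols[ok])] <- TRUE
  out
}

# ---- per-frame / per-video segmentation ------------------------------------

#' Segment one frame
#'
#' Vessel mask: red channel strictly below the threshold, then 8-connected
#' components with area strictly below \code{min_component_px} removed.
#' Exclusion mask: all pixels within \code{exclusion_radius_px} (euclidean,
#' inclusive) of a pixel saturated in all three channels. The two masks are
#' recorded separately; exclusion is applied downstream when widths are
#' measured.
#'
#' @param frame RGB raster (height x width x 3 integers).
#' @param cfg a [threshold_config] with \code{threshold} set.
#' @param bit_depth bits per channel (default 8).
#' @return Object of class \code{segmented_frame} with fields
#'   \code{vessel_mask}, \code{exclusion_mask}, \code{threshold_used}.
#' @export
segment_frame <- function(frame, cfg, bit_depth = 8L) {
  if (is.null(cfg$threshold))
    stop("cfg$threshold is not set; run auto_threshold() or supply one")
  maxval <- 2^bit_depth - 1
  vessel <- frame[, , 1L] < cfg$threshold
  vessel <- filter_small_components(vessel, cfg$min_component_px)
  excl <- saturation_exclusion(frame, cfg$saturation_fraction,
                               cfg$exclusion_radius_px, maxval)
  structure(list(vessel_mask = vessel, exclusion_mask = excl,
                 threshold_used = cfg$threshold),
            class = "segmented_frame")
}

#' Segment every frame of a clip
#'
#' One threshold for the whole video (per-frame adaptive thresholds are
#' deliberately not used). Emits the reproducibility log line recording
#' every parameter via \code{message()}.
#'
#' @param clip a [video_clip].
#' @param cfg a [threshold_config]; if \code{threshold} is \code{NULL} it is
#'   set by [auto_threshold] first.
#' @param quiet suppress the log line.
#' @return List of \code{segmented_frame}, one per frame, with the config
#'   used attached as attribute \code{"config"}.
#' @export
segment_video <- function(clip, cfg = threshold_config(), quiet = FALSE) {
  stopifnot(is_video_clip(clip))
  if (is.null(cfg$threshold))
    cfg$threshold <- auto_threshold(clip, cfg$n_sample_frames)
  segs <- vector("list", clip$frame_count)
  for (i in seq_len(clip$frame_count)) {
    segs[[i]] <- tryCatch(segment_frame(clip$frames[[i]], cfg, clip$bit_depth),
                          error = function(e)
                            stop("frame ", i, ": ", conditionMessage(e)))
  }
  if (!quiet) message(repro_log_line(cfg = cfg))
  attr(segs, "config") <- cfg
  segs
}

#' Render a segmentation confirmation montage
#'
#' Tiles \code{min(n_frames, frame_count)} equally spaced frames with the
#' vessel boundary in green and the exclusion zone in purple into one PNG,
#' the view used to verify a threshold before accepting it.
#'
#' @param clip a [video_clip].
#' @param segs output of [segment_video].
#' @param n_frames tiles requested (default 6; clamped to the frame count).
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
render_confirmation_montage <- function(clip, segs, n_frames = 6L, path) {
  stopifnot(is_video_clip(clip), n_frames >= 1L)
  idx <- sample_frame_indices(clip$frame_count, n_frames)
  tiles <- lapply(idx, function(i)
    overlay_frame(clip$frames[[i]], segs[[i]]$vessel_mask,
                  segs[[i]]$exclusion_mask))
  gap <- array(255L, c(clip$height, 2L, 3L))
  strip <- tiles[[1L]]
  for (t in tiles[-1L]) strip <- abind3(strip, gap, t)
  png::writePNG(strip / 255, path)
  invisible(path)
}

# bind rasters side by side along columns
abind3 <- function(...) {
  parts <- list(...)
  h <- dim(parts[[1L]])[1L]
  out <- array(0L, c(h, sum(vapply(parts, function(p) dim(p)[2L], 1L)), 3L))
  at <- 0L
  for (p in parts) {
    w <- dim(p)[2L]
    out[, at + seq_len(w), ] <- p
    at <- at + w
  }
  out
}
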