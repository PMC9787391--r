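# Contraction event detection on the mean-width time series.
#
# The trace is first smoothed over a sliding centred window (default 20
# frames). Two window filters are provided: a plain moving average (the
# default) and a two-means filter in which the values in each window are
# split into two clusters by exact 1-D 2-means and the centre value is
# replaced by the centroid of its cluster. The two-means filter keeps
# genuine level changes sharp, but on the roughly linear limbs of a real
# contraction its cluster assignment flips between windows, injecting
# non-monotone steps that defeat the run-based minima rule below — so the
# monotone-preserving moving average is the default detection trace.
#
# A trough (end-systole) is a frame whose preceding `run_frames` differences
# are all <= 0 with at least one < 0, and whose following `run_frames`
# differences are all >= 0 with at least one > 0. The runs are
# plateau-tolerant because integer-quantized widths plateau frequently;
# strict monotonicity is available via `strict = TRUE`. Each trough is then
# expanded forwards/backwards to where the curve flattens or reverses,
# giving the full contraction + re-filling cycle and the EDD/ESD readings.

#' Smooth a mean-width series
#'
#' @param raw numeric series of mean widths (px); \code{NA}s (excluded
#'   frames) are bridged by linear interpolation before smoothing and
#'   re-flagged afterwards in the \code{missing} field.
#' @param window_frames sliding window length (default 20); 1 = identity.
#' @param fps frames per second (carried for downstream unit conversion).
#' @param method \code{"mean"} (plain centred moving average, default) or
#'   \code{"kmeans"} (two-means window filter; edge-preserving but can
#'   inject non-monotone steps on contraction limbs).
#' @return Object of class \code{smoothed_series} with fields \code{raw},
#'   \code{smoothed}, \code{missing}, \code{window_frames}, \code{fps},
#'   \code{method}.
#' @export
smooth_series <- function(raw, window_frames = 20L, fps = NA_real_,
                          method = c("mean", "kmeans")) {
  method <- match.arg(method)
  n <- length(raw)
  if (window_frames < 1L) stop("'window_frames' must be >= 1")
  if (n < window_frames)
    stop("series (", n, " frames) shorter than the smoothing window (",
         window_frames, "); use a smaller window")
  missing <- is.na(raw)
  if (all(missing)) stop("series is entirely missing")
  x <- bridge_na(raw)
  half_before <- (window_frames - 1L) %/% 2L
  half_after <- window_frames - 1L - half_before
  sm <- x
  if (window_frames > 1L) {
    for (i in seq_len(n)) {
      win <- x[max(1L, i - half_before):min(n, i + half_after)]
      sm[i] <- if (method == "kmeans") two_means_value(win, x[i])
               else mean(win)
    }
  }
  structure(list(raw = raw, smoothed = sm, missing = missing,
                 window_frames = as.integer(window_frames),
                 fps = as.numeric(fps), method = method),
            class = "smoothed_series")
}

# linear interpolation across interior NAs, nearest value at the ends
bridge_na <- function(x) {
  if (!anyNA(x)) return(x)
  stats::approx(seq_along(x), x, xout = seq_along(x), rule = 2)$y
}

# exact 1-D 2-means of `win` (exhaustive over sorted split points, first
# minimal split wins); returns the centroid of the cluster containing
# `center_value`
two_means_value <- function(win, center_value) {
  v <- sort(win)
  m <- length(v)
  if (m < 2L || v[1L] == v[m]) return(center_value)
  cs <- cumsum(v)
  k <- seq_len(m - 1L)
  mu1 <- cs[k] / k
  mu2 <- (cs[m] - cs[k]) / (m - k)
  # within-cluster sum of squares for each split
  cs2 <- cumsum(v^2)
  wss <- (cs2[k] - k * mu1^2) + (cs2[m] - cs2[k] - (m - k) * mu2^2)
  kk <- which.min(wss)
  if (center_value <= v[kk]) mu1[kk] else mu2[kk]
}

#' @export
print.smoothed_series <- function(x, ...) {
  cat("<smoothed_series> ", length(x$raw), " frames, window ",
      x$window_frames, " (", x$method, "), fps = ", format(x$fps), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.smoothed_series <- function(x, ...) {
  tvals <- if (!is.na(x$fps)) (seq_along(x$raw) - 1) / x$fps
           else seq_along(x$raw) - 1
  graphics::plot(tvals, x$raw, type = "l", col = "grey60",
                 xlab = if (!is.na(x$fps)) "time (s)" else "frame",
                 ylab = "mean width (px)", ...)
  graphics::lines(tvals, x$smoothed, col = "purple", lwd = 2)
  invisible(x)
}

#' Detect trough (end-systolic) frames
#'
#' @param s a \code{smoothed_series} (or bare numeric vector).
#' @param run_frames length of the decreasing/increasing runs flanking a
#'   trough (default 10).
#' @param strict require strictly monotone runs instead of plateau-tolerant
#'   ones (default \code{FALSE}).
#' @return Integer vector of trough frame indices (1-based); within a flat
#'   trough plateau only the earliest frame is reported.
#' @export
find_minima <- function(s, run_frames = 10L, strict = FALSE) {
  x <- if (inherits(s, "smoothed_series")) s$smoothed else as.numeric(s)
  n <- length(x)
  if (run_frames < 1L) stop("'run_frames' must be >= 1")
  if (n <= 2L * run_frames) return(integer(0))
  d <- diff(x)
  ok <- logical(n)
  for (t in (run_frames + 1L):(n - run_frames)) {
    before <- d[(t - run_frames):(t - 1L)]
    after <- d[t:(t + run_frames - 1L)]
    ok[t] <- if (strict) all(before < 0) && all(after > 0)
             else all(before <= 0) && any(before < 0) &&
                  all(after >= 0) && any(after > 0)
  }
  cand <- which(ok)
  if (length(cand) <= 1L) return(cand)
  # collapse candidates connected by an all-flat stretch to the earliest
  keep <- rep(TRUE, length(cand))
  for (i in 2:length(cand)) {
    seg <- d[cand[i - 1L]:(cand[i] - 1L)]
    if (all(seg == 0)) keep[i] <- FALSE
  }
  cand[keep]
}

#' Expand a trough into a full contraction event
#'
#' Walks forward from the trough while the curve is strictly rising; the
#' first flattening or decrease ends the event (re-filling complete). Walks
#' backward the same way to find the start (end-diastole).
#'
#' Smoothing is essential for robust detection but biases the diameters it
#' reports: a centred moving average raises the value at a trough by roughly
#' the mean limb slope times half the window. With \code{measure = "raw"}
#' (the default) the event boundaries are therefore refined against the
#' unsmoothed trace — the trough moves to the raw minimum within half a
#' smoothing window ("immediately after contraction": earliest tie wins),
#' the start to the raw maximum ("immediately before contraction": latest
#' tie wins) — and EDD/ESD are read there. \code{measure = "smoothed"}
#' reads them from the smoothed trace at the detected frames instead.
#'
#' @param s a \code{smoothed_series} (or bare numeric vector, in which case
#'   the two modes coincide).
#' @param trough a trough frame from [find_minima].
#' @param measure where diameters are read: \code{"raw"} (refined against
#'   the unsmoothed trace, default) or \code{"smoothed"}.
#' @return One-row data.frame: \code{start_frame}, \code{trough_frame},
#'   \code{end_frame} (1-based), \code{edd_px}, \code{esd_px},
#'   \code{amplitude_px}, \code{truncated}.
#' @export
expand_event <- function(s, trough, measure = c("raw", "smoothed")) {
  measure <- match.arg(measure)
  is_ss <- inherits(s, "smoothed_series")
  x <- if (is_ss) s$smoothed else as.numeric(s)
  n <- length(x)
  stopifnot(trough >= 1L, trough <= n)
  e <- trough
  while (e < n && x[e + 1L] == x[e]) e <- e + 1L   # skip a flat trough bottom
  while (e < n && x[e + 1L] > x[e]) e <- e + 1L
  b <- trough
  while (b > 1L && x[b - 1L] > x[b]) b <- b - 1L
  truncated <- (e == n && (n == trough || x[n] > x[n - 1L])) ||
               (b == 1L && (trough == 1L || x[1L] > x[2L]))
  tr <- as.integer(trough)
  half <- if (is_ss) s$window_frames %/% 2L else 0L
  if (measure == "raw" && is_ss && half > 0L) {
    r <- bridge_na(s$raw)
    lo <- max(b, tr - half); hi <- min(e, tr + half)
    win <- lo:hi
    tr <- win[which.min(r[win])]                       # earliest raw minimum
    s_lo <- max(1L, b - half); s_hi <- max(s_lo, min(b + half, tr - 1L))
    win <- s_lo:s_hi
    b <- win[max(which(r[win] == max(r[win])))]        # latest raw maximum
    edd <- r[b]; esd <- r[tr]
  } else {
    edd <- x[b]; esd <- x[tr]
  }
  data.frame(start_frame = b, trough_frame = tr,
             end_frame = e,
             edd_px = edd, esd_px = esd,
             amplitude_px = edd - esd,
             truncated = truncated)
}

#' Detect and expand all contraction events in a series
#'
#' @inheritParams find_minima
#' @inheritParams expand_event
#' @return data.frame of events (possibly 0 rows), one row per trough, in
#'   time order; columns as in [expand_event].
#' @export
detect_events <- function(s, run_frames = 10L, strict = FALSE,
                          measure = c("raw", "smoothed")) {
  measure <- match.arg(measure)
  troughs <- find_minima(s, run_frames, strict)
  if (length(troughs) == 0L)
    return(expand_event(c(0, 0), 1L)[0L, ])
  do.call(rbind, lapply(troughs, function(t) expand_event(s, t, measure)))
}

#' Filter events by amplitude and duration
#'
#' Events whose mean diameter decreased by less than \code{min_amplitude_px}
#' are too small to be a viable lymphatic contraction; events lasting more
#' than \code{max_duration_frames} are too long. Both bounds are inclusive
#' for kept events (amplitude exactly 1 px and duration exactly 110 frames
#' are kept).
#'
#' @param events data.frame from [detect_events].
#' @param min_amplitude_px minimum EDD-to-ESD amplitude, px (default 1).
#' @param max_duration_frames maximum \code{end - start} span, frames
#'   (default 110).
#' @return The kept events, with the rejected ones (plus a \code{reason}
#'   column) in attribute \code{"rejected"}.
#' @export
filter_events <- function(events, min_amplitude_px = 1,
                          max_duration_frames = 110L) {
  if (nrow(events) == 0L) {
    attr(events, "rejected") <- cbind(events, reason = character(0))
    return(events)
  }
  duration <- events$end_frame - events$start_frame
  reason <- rep(NA_character_, nrow(events))
  reason[duration > max_duration_frames] <- "duration"
  reason[events$amplitude_px < min_amplitude_px] <- "amplitude"
  kept <- events[is.na(reason), , drop = FALSE]
  rejected <- cbind(events[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  rownames(kept) <- NULL
  attr(kept, "rejected") <- rejected
  kept
}
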