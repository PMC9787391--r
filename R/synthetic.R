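# Ground-truthed synthetic vessel videos.
#
# Emulates the imaging this workflow targets: a dark (low red-channel)
# dye-filled vessel running vertically on a brighter mesentery background,
# with time-varying width, spatially heterogeneous contraction amplitude,
# saturated glare discs and sensor noise. Edges are rendered with sub-pixel
# coverage shading (anti-aliasing) so threshold placement has the realistic
# +/- 1 px effect. The generator returns exact analytic widths and event
# times, so every pipeline stage can be tested against ground truth.

#' Synthetic vessel scene description
#'
#' Width at position y and frame t is
#' \code{baseline_width_px[y] - amplitude_px[y] * pulse[t]}, with
#' \code{pulse} in \code{[0, 1]} (1 = fully contracted).
#'
#' @param n_frames,fps,height,width video geometry; \code{height} is the
#'   vessel-axis direction (positions).
#' @param baseline_width_px diastolic width per position (scalar or length
#'   \code{height} vector).
#' @param amplitude_px contraction amplitude per position (scalar or vector).
#' @param pulse numeric vector of length \code{n_frames} in \code{[0, 1]}.
#' @param truth_events optional data.frame (\code{start_frame},
#'   \code{trough_frame}, \code{end_frame}, 1-based) recording the event
#'   structure of \code{pulse}, carried through as ground truth.
#' @param background_intensity,vessel_intensity red-channel levels of the
#'   mesentery and the dye-filled vessel (vessel must be darker).
#' @param noise_sd additive Gaussian noise SD (intensity levels); applied to
#'   the red channel only unless \code{noise_channels = "rgb"}.
#' @param noise_channels \code{"red"} (default) or \code{"rgb"}.
#' @param glare list of glare discs, each \code{list(center = c(row, col),
#'   radius = r)} (1-based); rendered as saturated white.
#' @param center_col continuous column coordinate of the vessel midline
#'   (default: frame centre).
#' @param seed RNG seed; fixes the rendered video bit-for-bit.
#' @return Object of class \code{vessel_scene}.
#' @export
vessel_scene <- function(n_frames, fps = 22, height = 120L, width = 40L,
                         baseline_width_px = 15, amplitude_px = 9,
                         pulse = numeric(n_frames),
                         truth_events = NULL,
                         background_intensity = 200L, vessel_intensity = 40L,
                         noise_sd = 0, noise_channels = c("red", "rgb"),
                         glare = list(), center_col = NULL, seed = 1L) {
  noise_channels <- match.arg(noise_channels)
  baseline <- rep_len(baseline_width_px, height)
  amplitude <- rep_len(amplitude_px, height)
  if (vessel_intensity >= background_intensity)
    stop("vessel must be darker than the background in the red channel")
  if (any(baseline - amplitude < 0))
    stop("baseline - amplitude must be >= 0 at every position")
  if (length(pulse) != n_frames) stop("'pulse' must have length n_frames")
  if (any(pulse < 0 | pulse > 1)) stop("'pulse' must lie in [0, 1]")
  if (is.null(center_col)) center_col <- width / 2
  structure(list(n_frames = as.integer(n_frames), fps = as.numeric(fps),
                 height = as.integer(height), width = as.integer(width),
                 baseline_width_px = baseline, amplitude_px = amplitude,
                 pulse = as.numeric(pulse), truth_events = truth_events,
                 background_intensity = as.integer(background_intensity),
                 vessel_intensity = as.integer(vessel_intensity),
                 noise_sd = as.numeric(noise_sd),
                 noise_channels = noise_channels,
                 glare = glare, center_col = as.numeric(center_col),
                 seed = as.integer(seed)),
            class = "vessel_scene")
}

#' @export
print.vessel_scene <- function(x, ...) {
  cat("<vessel_scene> ", x$n_frames, " frames @ ", x$fps, " fps, ",
      x$height, " x ", x$width, " px, ", length(x$glare), " glare disc(s), ",
      "noise_sd = ", x$noise_sd, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Render a synthetic scene to a clip plus ground truth
#'
#' @param scene a [vessel_scene].
#' @return List: \code{clip} (a [video_clip]), \code{truth_widths}
#'   (n_frames x height analytic width matrix), \code{truth_events}
#'   (data.frame with frames, \code{edd_px}, \code{esd_px},
#'   \code{amplitude_px} of the spatial mean trace), and \code{pulse}.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "vessel_scene"))
  h <- scene$height; w <- scene$width
  bg <- scene$background_intensity; vi <- scene$vessel_intensity
  xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)     # column cell starts
  truth_widths <- matrix(scene$baseline_width_px, scene$n_frames, h,
                         byrow = TRUE) -
    outer(scene$pulse, scene$amplitude_px)
  glare_mask <- matrix(FALSE, h, w)
  for (g in scene$glare) {
    rr <- matrix(seq_len(h), h, w) - g$center[1L]
    cc <- matrix(seq_len(w), h, w, byrow = TRUE) - g$center[2L]
    glare_mask <- glare_mask | (rr^2 + cc^2 <= g$radius^2)
  }
  set.seed(scene$seed)
  clamp <- function(m) { m[m < 0] <- 0; m[m > 255] <- 255; m }
  frames <- vector("list", scene$n_frames)
  for (t in seq_len(scene$n_frames)) {
    wt <- truth_widths[t, ]
    left <- scene$center_col - wt / 2
    right <- scene$center_col + wt / 2
    cov <- pmin(xs + 1, right) - pmax(xs, left)        # recycles over rows
    cov[cov < 0] <- 0; cov[cov > 1] <- 1
    red <- bg - (bg - vi) * cov
    green <- 180 - 60 * cov
    blue <- matrix(230, h, w)
    if (scene$noise_sd > 0) {
      red <- red + stats::rnorm(h * w, sd = scene$noise_sd)
      if (scene$noise_channels == "rgb") {
        green <- green + stats::rnorm(h * w, sd = scene$noise_sd)
        blue <- blue + stats::rnorm(h * w, sd = scene$noise_sd)
      }
    }
    fr <- array(0L, c(h, w, 3L))
    fr[, , 1L] <- as.integer(round(clamp(red)))
    fr[, , 2L] <- as.integer(round(clamp(green)))
    fr[, , 3L] <- as.integer(round(clamp(blue)))
    if (any(glare_mask)) for (ch in 1:3) {
      plane <- fr[, , ch]; plane[glare_mask] <- 255L; fr[, , ch] <- plane
    }
    frames[[t]] <- fr
  }
  truth_events <- scene$truth_events
  if (!is.null(truth_events)) {
    truth_events$edd_px <- mean(scene$baseline_width_px)
    truth_events$esd_px <- mean(scene$baseline_width_px - scene$amplitude_px)
    truth_events$amplitude_px <- mean(scene$amplitude_px)
  }
  list(clip = video_clip(frames, fps = scene$fps),
       truth_widths = truth_widths, truth_events = truth_events,
       pulse = scene$pulse, scene = scene)
}

#' Build a pulse train with known event structure
#'
#' Each cycle: a flat diastolic plateau, a linear contraction (pulse rising
#' 0 to 1), a linear re-filling (1 back to 0), then rest until the next
#' cycle. Returns the pulse vector plus the exact event frames.
#'
#' @param n_frames series length.
#' @param starts 1-based frames at which each contraction begins (end of
#'   diastole).
#' @param contraction_frames,refill_frames lengths of the falling and rising
#'   limbs, in frames.
#' @return List \code{pulse} (numeric vector) and \code{events}
#'   (data.frame with \code{start_frame}, \code{trough_frame},
#'   \code{end_frame}).
#' @export
pulse_train <- function(n_frames, starts, contraction_frames = 60L,
                        refill_frames = 30L) {
  pulse <- numeric(n_frames)
  ev <- data.frame(start_frame = as.integer(starts),
                   trough_frame = as.integer(starts + contraction_frames),
                   end_frame = as.integer(starts + contraction_frames +
                                            refill_frames))
  if (any(ev$end_frame > n_frames))
    stop("pulse train does not fit in n_frames")
  for (i in seq_len(nrow(ev))) {
    s <- ev$start_frame[i]
    pulse[s + 0:contraction_frames] <- (0:contraction_frames) / contraction_frames
    pulse[ev$trough_frame[i] + 0:refill_frames] <-
      1 - (0:refill_frames) / refill_frames
  }
  list(pulse = pulse, events = ev)
}

#' The default integration-test scene
#'
#' A 30 s, 22 FPS recording of a vertically oriented vessel: diastolic
#' diameter 15 px, four contractions down to 6 px (mean amplitude 9 px)
#' spaced 140 frames apart (6.36 s, i.e. 9.43 contractions/min), amplitude
#' varying linearly from 6 to 12 px along the vessel, mild red-channel
#' noise and one glare disc beside the vessel. At 13.7 um/px this spans
#' mean diameters of about 82-205 um, the regime the workflow was designed
#' for.
#'
#' @param seed RNG seed for the rendered noise (default 1).
#' @param noise_sd sensor noise SD (default 2 intensity levels).
#' @return A [vessel_scene].
#' @export
preset_paper_like <- function(seed = 1L, noise_sd = 2) {
  n_frames <- 660L
  height <- 150L
  pt <- pulse_train(n_frames, starts = 31L + 140L * (0:3),
                    contraction_frames = 60L, refill_frames = 30L)
  vessel_scene(
    n_frames = n_frames, fps = 22, height = height, width = 40L,
    baseline_width_px = 15,
    amplitude_px = seq(6, 12, length.out = height),
    pulse = pt$pulse, truth_events = pt$events,
    background_intensity = 200L, vessel_intensity = 40L,
    noise_sd = noise_sd, glare = list(list(center = c(75, 35), radius = 4)),
    seed = seed)
}
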