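# Shared fixtures, built in code at test time.

# a flat RGB frame
flat_frame <- function(h, w, rgb = c(200L, 180L, 230L)) {
  fr <- array(0L, c(h, w, 3L))
  for (ch in 1:3) fr[, , ch] <- rgb[ch]
  fr
}

# frame with a vertical dark band (the "vessel") in given columns
vessel_frame <- function(h, w, cols, vessel_red = 40L, bg_red = 200L) {
  fr <- flat_frame(h, w, c(bg_red, 180L, 230L))
  fr[, cols, 1L] <- vessel_red
  fr
}

# a small, fast contracting-vessel scene for unit tests:
# 300 frames @ 22 fps, 60 positions, two contractions
small_scene <- function(noise_sd = 0, seed = 1L, amplitude = 9,
                        glare = list()) {
  pt <- pulse_train(300L, starts = c(31L, 171L),
                    contraction_frames = 60L, refill_frames = 30L)
  vessel_scene(n_frames = 300L, fps = 22, height = 60L, width = 40L,
               baseline_width_px = 15, amplitude_px = amplitude,
               pulse = pt$pulse, truth_events = pt$events,
               noise_sd = noise_sd, glare = glare, seed = seed)
}

# the full paper-like preset rendered + segmented once per test run
.preset_cache <- new.env(parent = emptyenv())
preset_fixture <- function() {
  if (is.null(.preset_cache$fx)) {
    scene <- preset_paper_like()
    r <- render_scene(scene)
    segs <- segment_video(r$clip, quiet = TRUE)
    profile <- build_profile(segs, fps = r$clip$fps, calib = 0.0137)
    .preset_cache$fx <- list(scene = scene, rendered = r, segs = segs,
                             profile = profile,
                             mean_series = mean_width_series(profile))
  }
  .preset_cache$fx
}
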