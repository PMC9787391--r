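# End-to-end analysis entry points and the run configuration.
#
# A run is exactly reproducible from its saved configuration plus the input
# file: every stage is deterministic given the config, and the
# reproducibility log line prints all parameters in one machine-parseable
# line (the same information the config file stores).

#' Analysis run configuration
#'
#' @param input path to the video (or still image for [threshold_image]).
#' @param roi a [roi_spec], the textual \code{"cx,cy,length,width,angle"}
#'   form, or \code{NULL} to analyze the whole frame.
#' @param threshold manual red-channel threshold; \code{NULL} = automatic.
#' @param n_sample_frames,min_component_px,saturation_fraction,exclusion_radius_px
#'   segmentation parameters (see [threshold_config]).
#' @param window_frames smoothing window (default 20).
#' @param run_frames minima run length (default 10).
#' @param min_amplitude_px,max_duration_frames event filters (defaults 1 px,
#'   110 frames).
#' @param section_len_px section length for positional analysis (default 30).
#' @param mm_per_px calibration; \code{NA} = uncalibrated (outputs in px).
#' @param fps frame-rate override; \code{NULL} = use container metadata.
#' @param out_dir output directory.
#' @param seed RNG seed recorded with the run.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(input, roi = NULL, threshold = NULL,
                       n_sample_frames = 6L, min_component_px = 10L,
                       saturation_fraction = 0.99, exclusion_radius_px = 5,
                       window_frames = 20L, run_frames = 10L,
                       min_amplitude_px = 1, max_duration_frames = 110L,
                       section_len_px = 30L, mm_per_px = NA_real_,
                       fps = NULL, out_dir = tempfile("lymphpulse_run"),
                       seed = 1L) {
  if (is.character(roi)) roi <- parse_roi(roi)
  structure(list(input = input, roi = roi, threshold = threshold,
                 n_sample_frames = as.integer(n_sample_frames),
                 min_component_px = as.numeric(min_component_px),
                 saturation_fraction = as.numeric(saturation_fraction),
                 exclusion_radius_px = as.numeric(exclusion_radius_px),
                 window_frames = as.integer(window_frames),
                 run_frames = as.integer(run_frames),
                 min_amplitude_px = as.numeric(min_amplitude_px),
                 max_duration_frames = as.integer(max_duration_frames),
                 section_len_px = as.integer(section_len_px),
                 mm_per_px = as.numeric(mm_per_px), fps = fps,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

as_threshold_config <- function(cfg) {
  threshold_config(threshold = cfg$threshold,
                   n_sample_frames = cfg$n_sample_frames,
                   min_component_px = cfg$min_component_px,
                   saturation_fraction = cfg$saturation_fraction,
                   exclusion_radius_px = cfg$exclusion_radius_px)
}

#' One-line reproducibility record
#'
#' A single machine-parseable line with every parameter of the analysis;
#' printing it (as the pipeline stages do) lets a run be reproduced or
#' batch-applied exactly.
#'
#' @param cfg a [run_config] or [threshold_config].
#' @param ... extra \code{name = value} fields appended to the line.
#' @return The log line (character scalar).
#' @export
repro_log_line <- function(cfg = NULL, ...) {
  fields <- list(...)
  if (!is.null(cfg)) {
    base <- unclass(cfg)
    base$roi <- if (!is.null(base$roi)) format(base$roi) else NULL
    base$threshold <- if (is.null(base$threshold)) "auto" else base$threshold
    fields <- c(base[!vapply(base, is.null, TRUE)], fields)
  }
  paste0("lymphpulse | ",
         paste(names(fields),
               vapply(fields, function(v) paste(format(v, trim = TRUE),
                                                collapse = ";"),
                      character(1L)),
               sep = "=", collapse = " "))
}

#' Save / load a run configuration
#'
#' Plain \code{key: value} text; [read_run_config] restores an equivalent
#' \code{run_config}, which together with the input file reproduces the run
#' exactly.
#'
#' @param cfg a [run_config].
#' @param path file path.
#' @return \code{path} / a \code{run_config}.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$roi <- if (!is.null(x$roi)) format(x$roi) else NULL
  lines <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    paste0(nm, ": ", if (is.null(v)) "NULL"
           else paste(format(v, digits = 17, trim = TRUE), collapse = ","))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([a-z_]+): (.*)$", lines))
  vals <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  get_num <- function(nm) {
    v <- vals[[nm]]
    if (is.null(v) || v == "NULL" || v == "NA") NA_real_ else as.numeric(v)
  }
  run_config(
    input = vals$input,
    roi = if (!identical(vals$roi, "NULL") && !is.null(vals$roi)) vals$roi,
    threshold = if (!identical(vals$threshold, "NULL")) get_num("threshold"),
    n_sample_frames = get_num("n_sample_frames"),
    min_component_px = get_num("min_component_px"),
    saturation_fraction = get_num("saturation_fraction"),
    exclusion_radius_px = get_num("exclusion_radius_px"),
    window_frames = get_num("window_frames"),
    run_frames = get_num("run_frames"),
    min_amplitude_px = get_num("min_amplitude_px"),
    max_duration_frames = get_num("max_duration_frames"),
    section_len_px = get_num("section_len_px"),
    mm_per_px = get_num("mm_per_px"),
    fps = if (!identical(vals$fps, "NULL")) get_num("fps"),
    out_dir = vals$out_dir,
    seed = get_num("seed"))
}

# ---- core analysis object ---------------------------------------------------

#' Detect and summarize contractions in a mean-width series
#'
#' The core analysis: smooth the series, find troughs, expand them into
#' contraction events, apply the amplitude/duration filters, and derive the
#' contractile parameters. Returns a classed object with print, summary and
#' plot methods.
#'
#' @param raw numeric mean-width series (px), \code{NA} = excluded frame.
#' @param fps frames per second (required).
#' @param calib a [calibration] / mm-per-px scalar, or \code{NULL} for px.
#' @param window_frames,run_frames,min_amplitude_px,max_duration_frames,smooth_method
#'   detection parameters (defaults 20, 10, 1 px, 110, "kmeans").
#' @param strict require strictly monotone minima runs (default FALSE,
#'   plateau-tolerant).
#' @param measure where event diameters are read (see [expand_event]):
#'   \code{"raw"} (default) or \code{"smoothed"}.
#' @return Object of class \code{contraction_analysis}: fields
#'   \code{series} (\code{smoothed_series}), \code{events},
#'   \code{rejected}, \code{summary} (\code{contractile_summary}) and the
#'   parameters used.
#' @export
analyze_contractions <- function(raw, fps, calib = NULL,
                                 window_frames = 20L, run_frames = 10L,
                                 min_amplitude_px = 1,
                                 max_duration_frames = 110L,
                                 smooth_method = "mean", strict = FALSE,
                                 measure = c("raw", "smoothed")) {
  measure <- match.arg(measure)
  if (length(raw) < 2L || is.na(fps))
    stop("time-domain analysis needs >= 2 frames and a frame rate")
  s <- smooth_series(raw, window_frames, fps = fps, method = smooth_method)
  ev <- detect_events(s, run_frames, strict = strict, measure = measure)
  kept <- filter_events(ev, min_amplitude_px, max_duration_frames)
  structure(list(series = s, events = kept,
                 rejected = attr(kept, "rejected"),
                 summary = summarize_events(kept, s, calib = calib,
                                            measure = measure),
                 params = list(window_frames = window_frames,
                               run_frames = run_frames,
                               min_amplitude_px = min_amplitude_px,
                               max_duration_frames = max_duration_frames,
                               smooth_method = smooth_method,
                               strict = strict)),
            class = "contraction_analysis")
}

#' @export
print.contraction_analysis <- function(x, ...) {
  cat("<contraction_analysis> ", length(x$series$raw), " frames @ ",
      format(x$series$fps), " fps; ", nrow(x$events), " event(s) kept, ",
      nrow(x$rejected), " rejected\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
summary.contraction_analysis <- function(object, ...) object$summary

#' @export
plot.contraction_analysis <- function(x, ...) {
  plot(x$series, ...)
  if (nrow(x$events) > 0L) {
    tx <- function(fr) (fr - 1) / x$series$fps
    graphics::points(tx(x$events$trough_frame),
                     x$events$esd_px, col = "red", pch = 16)
    graphics::points(tx(x$events$start_frame),
                     x$events$edd_px, col = "darkgreen", pch = 17)
    graphics::segments(tx(x$events$start_frame), x$events$edd_px,
                       tx(x$events$end_frame), x$events$edd_px,
                       col = "darkgreen", lty = 3)
  }
  invisible(x)
}

# ---- output writers ---------------------------------------------------------

# events table with 0-based frame indices and both px and physical units
events_out_table <- function(analysis) {
  ev <- analysis$events
  su <- analysis$summary
  fps <- analysis$series$fps
  k <- if (su$units == "mm") su$mm_per_px else NA_real_
  data.frame(
    event = seq_len(nrow(ev)),
    start_frame = ev$start_frame - 1L, trough_frame = ev$trough_frame - 1L,
    end_frame = ev$end_frame - 1L,
    start_s = (ev$start_frame - 1L) / fps,
    trough_s = (ev$trough_frame - 1L) / fps,
    end_s = (ev$end_frame - 1L) / fps,
    edd_px = ev$edd_px, esd_px = ev$esd_px, amplitude_px = ev$amplitude_px,
    edd_mm = ev$edd_px * k, esd_mm = ev$esd_px * k,
    amplitude_mm = ev$amplitude_px * k,
    truncated = ev$truncated)
}

summary_out_table <- function(summary, section = NA) {
  s <- summary$stats
  wide <- as.list(stats::setNames(s$mean, paste0(s$parameter, "_mean")))
  wide_sd <- as.list(stats::setNames(s$sd, paste0(s$parameter, "_sd")))
  data.frame(section = section, n_contractions = summary$n_contractions,
             cf_per_min = summary$cf_per_min,
             fpf_pct_per_min = summary$fpf_pct_per_min,
             peak_mm = summary$peak_mm, nadir_mm = summary$nadir_mm,
             units = summary$units,
             as.data.frame(wide), as.data.frame(wide_sd))
}

# ---- pipeline entry points --------------------------------------------------

load_and_roi <- function(cfg) {
  clip <- read_video(cfg$input, fps = cfg$fps)
  if (!is.null(cfg$roi)) clip <- extract_roi(clip, cfg$roi)
  clip
}

#' Whole-ROI contraction quantification
#'
#' Runs extract -> segment -> width profile -> smooth -> detect -> filter ->
#' summarize on the mean width of the whole ROI and writes the trace plot,
#' the widths/events/summary CSVs, the saved config and the reproducibility
#' log line to \code{cfg$out_dir}.
#'
#' @param cfg a [run_config].
#' @param quiet suppress the log line.
#' @return The \code{contraction_analysis}, invisibly; written file paths in
#'   attribute \code{"paths"}.
#' @export
quantify_mean_width <- function(cfg, quiet = FALSE) {
  clip <- load_and_roi(cfg)
  stop_if_still(clip)
  segs <- segment_video(clip, as_threshold_config(cfg), quiet = TRUE)
  cfg$threshold <- attr(segs, "config")$threshold
  profile <- build_profile(segs, fps = clip$fps, calib = cfg$mm_per_px)
  analysis <- analyze_contractions(
    mean_width_series(profile), fps = clip$fps,
    calib = if (!is.na(cfg$mm_per_px)) cfg$mm_per_px,
    window_frames = cfg$window_frames, run_frames = cfg$run_frames,
    min_amplitude_px = cfg$min_amplitude_px,
    max_duration_frames = cfg$max_duration_frames)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    widths = file.path(cfg$out_dir, "widths.csv"),
    events = file.path(cfg$out_dir, "events.csv"),
    summary = file.path(cfg$out_dir, "summary.csv"),
    trace = file.path(cfg$out_dir, "trace.png"),
    config = file.path(cfg$out_dir, "config.txt"))
  write_width_csv(profile, paths$widths)
  utils::write.csv(events_out_table(analysis), paths$events, row.names = FALSE)
  utils::write.csv(summary_out_table(analysis$summary), paths$summary,
                   row.names = FALSE)
  grDevices::png(paths$trace, width = 900, height = 400, type = "cairo")
  plot(analysis)
  grDevices::dev.off()
  write_run_config(cfg, paths$config)
  if (!quiet) message(repro_log_line(cfg, n_events = nrow(analysis$events),
                                     n_rejected = nrow(analysis$rejected)))
  attr(analysis, "paths") <- paths
  invisible(analysis)
}

#' Positional (along-vessel) contraction quantification
#'
#' Produces the kymograph heatmap, the per-position peak-minus-nadir
#' profile, independent per-section event detection and summaries, and the
#' event overlay for manual review.
#'
#' @param cfg a [run_config].
#' @param quiet suppress the log line.
#' @return List (class \code{position_analysis}): \code{profile},
#'   \code{max_change}, \code{sections} (a \code{section_results}),
#'   \code{section_table} (long per-event table) and \code{paths}.
#' @export
quantify_width_position <- function(cfg, quiet = FALSE) {
  clip <- load_and_roi(cfg)
  stop_if_still(clip)
  segs <- segment_video(clip, as_threshold_config(cfg), quiet = TRUE)
  cfg$threshold <- attr(segs, "config")$threshold
  profile <- build_profile(segs, fps = clip$fps, calib = cfg$mm_per_px)
  sections <- make_sections(profile$n_positions, cfg$section_len_px)
  results <- per_section_pipeline(
    profile, sections, window_frames = cfg$window_frames,
    run_frames = cfg$run_frames, min_amplitude_px = cfg$min_amplitude_px,
    max_duration_frames = cfg$max_duration_frames)
  mc <- max_change_profile(profile)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    heatmap = file.path(cfg$out_dir, "heatmap.png"),
    peak_nadir = file.path(cfg$out_dir, "peak_nadir.png"),
    peak_nadir_csv = file.path(cfg$out_dir, "peak_nadir.csv"),
    sections = file.path(cfg$out_dir, "section_summaries.csv"),
    section_events = file.path(cfg$out_dir, "section_events.csv"),
    overlay = file.path(cfg$out_dir, "event_overlay.png"),
    config = file.path(cfg$out_dir, "config.txt"))
  render_heatmap(profile, paths$heatmap)
  unit <- attr(mc, "units")
  grDevices::png(paths$peak_nadir, width = 500, height = 600, type = "cairo")
  graphics::plot(mc, seq_along(mc) - 1, type = "l", ylim = rev(range(c(0, length(mc) - 1))),
                 xlab = paste0("peak - nadir (", unit, ")"),
                 ylab = "position from top (px)",
                 main = "Maximum diameter change along the vessel")
  b <- sections$boundaries
  graphics::abline(h = b$start[-1L], col = "red", lty = 2)
  grDevices::dev.off()
  utils::write.csv(data.frame(position_index = seq_along(mc) - 1L,
                              peak_minus_nadir = as.numeric(mc),
                              units = unit),
                   paths$peak_nadir_csv, row.names = FALSE)
  sec_rows <- lapply(seq_along(results$summaries), function(i) {
    s <- results$summaries[[i]]
    if (is.null(s)) return(NULL)
    summary_out_table(s, section = i)
  })
  utils::write.csv(do.call(rbind, sec_rows), paths$sections, row.names = FALSE)
  utils::write.csv(compare_sections(results$summaries), paths$section_events,
                   row.names = FALSE)
  render_event_overlay(profile, results, paths$overlay)
  write_run_config(cfg, paths$config)
  if (!quiet) message(repro_log_line(cfg, n_sections = nrow(b)))
  out <- list(profile = profile, max_change = mc, sections = results,
              section_table = compare_sections(results$summaries),
              paths = paths)
  class(out) <- "position_analysis"
  invisible(out)
}

#' Diameter along the length of a vessel in a still image
#'
#' Single-image mode: segments one frame and reports the vessel width at
#' every pixel row (px; mm too when calibrated), with glare-affected rows
#' excluded. Writes a segmentation overlay PNG and the per-position CSV.
#'
#' @param cfg a [run_config] whose \code{input} is a still image (or a
#'   1-frame video); \code{threshold = NULL} uses the automatic value from
#'   the image itself.
#' @param quiet suppress the log line.
#' @return data.frame \code{position_index} (0-based), \code{width_px},
#'   \code{excluded_flag} (and \code{width_mm} when calibrated), invisibly;
#'   paths in attribute \code{"paths"}.
#' @export
threshold_image <- function(cfg, quiet = FALSE) {
  clip <- load_and_roi(cfg)
  segs <- segment_video(clip, as_threshold_config(cfg), quiet = TRUE)
  cfg$threshold <- attr(segs, "config")$threshold
  rw <- row_widths(segs[[1L]])
  df <- data.frame(position_index = seq_along(rw$width) - 1L,
                   width_px = ifelse(rw$missing, NA_real_, rw$width),
                   excluded_flag = rw$missing)
  if (!is.na(cfg$mm_per_px)) df$width_mm <- df$width_px * cfg$mm_per_px
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(widths = file.path(cfg$out_dir, "diameter_along_length.csv"),
                overlay = file.path(cfg$out_dir, "segmentation_overlay.png"),
                plot = file.path(cfg$out_dir, "diameter_along_length.png"),
                config = file.path(cfg$out_dir, "config.txt"))
  utils::write.csv(df, paths$widths, row.names = FALSE, na = "")
  png::writePNG(overlay_frame(clip$frames[[1L]], segs[[1L]]$vessel_mask,
                              segs[[1L]]$exclusion_mask) / 255,
                paths$overlay)
  grDevices::png(paths$plot, width = 500, height = 600, type = "cairo")
  graphics::plot(df$width_px, df$position_index, type = "l",
                 ylim = rev(range(df$position_index)),
                 xlab = "width (px)", ylab = "position from top (px)",
                 main = "Diameter along the vessel")
  grDevices::dev.off()
  write_run_config(cfg, paths$config)
  if (!quiet) message(repro_log_line(cfg))
  attr(df, "paths") <- paths
  invisible(df)
}
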