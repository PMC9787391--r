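# Contractile parameters derived from detected events.
#
# Per event (diameters in mm via the calibration):
#   EDD  end-diastolic diameter, the smoothed width at the event start
#   ESD  end-systolic diameter, the smoothed width at the trough
#   CA   contraction amplitude              = EDD - ESD
#   EF   ejection fraction                  = (EDD^2 - ESD^2) / EDD^2 * 100
#        (fraction of cross-sectional area expelled, circular cross-section)
#   contraction duration                    = (trough - start) / fps
#   muscle shortening speed                 = CA / contraction duration
# and, for events with a predecessor:
#   relaxation duration                     = (start - previous trough) / fps
#   filling speed                           = (EDD - previous ESD) / relaxation duration
#   percent re-filling                      = (EDD - previous ESD) / previous CA * 100
# Aggregates:
#   CF   contraction frequency  = 1 / mean(trough-to-trough interval), min^-1
#   FPF  fractional pump flow   = mean per-event EF x CF  (% min^-1)
#   peak / nadir = max / min of the smoothed series over the whole recording,
#   whether associated with a contraction or not.

#' Summarize contraction events into contractile parameters
#'
#' @param events filtered events data.frame (see [filter_events]).
#' @param series the \code{smoothed_series} the events were detected on
#'   (source of peak/nadir and of \code{fps} unless overridden).
#' @param calib a [calibration] or bare mm-per-px scalar; \code{NULL} keeps
#'   everything in px (column names still say \code{_mm}; the \code{units}
#'   field records which applies).
#' @param fps frames per second; defaults to \code{series$fps}.
#' @param fpf_mode \code{"per_event"} (FPF = mean of per-event EF times CF,
#'   default) or \code{"aggregate"} (EF of the mean diameters times CF).
#' @param cf_mode interval definition for CF: \code{"trough"}
#'   (trough-to-trough, default) or \code{"start"} (EDD-to-EDD).
#' @param measure source of the whole-recording peak/nadir: \code{"raw"}
#'   (the measured trace, default) or \code{"smoothed"}; matches the
#'   \code{measure} mode used in [expand_event].
#' @return Object of class \code{contractile_summary}: \code{n_contractions},
#'   \code{cf_per_min}, \code{fpf_pct_per_min}, \code{peak_mm},
#'   \code{nadir_mm}, a per-event data.frame \code{per_event}, and
#'   \code{stats} (mean and SD per parameter). Predecessor-dependent fields
#'   are \code{NA} for the first event; CF and FPF are \code{NA} with fewer
#'   than 2 events.
#' @export
summarize_events <- function(events, series, calib = NULL, fps = NULL,
                             fpf_mode = c("per_event", "aggregate"),
                             cf_mode = c("trough", "start"),
                             measure = c("raw", "smoothed")) {
  fpf_mode <- match.arg(fpf_mode)
  cf_mode <- match.arg(cf_mode)
  measure <- match.arg(measure)
  if (is.null(fps)) fps <- if (inherits(series, "smoothed_series"))
    series$fps else NA_real_
  sm <- if (!inherits(series, "smoothed_series")) as.numeric(series)
        else if (measure == "raw") series$raw else series$smoothed
  k <- as_mm_per_px(calib)
  units <- if (is.na(k)) "px" else "mm"
  if (is.na(k)) k <- 1
  n <- nrow(events)

  per_event <- data.frame(
    event = seq_len(n),
    start_frame = events$start_frame, trough_frame = events$trough_frame,
    end_frame = events$end_frame,
    edd_mm = events$edd_px * k, esd_mm = events$esd_px * k,
    ca_mm = events$amplitude_px * k)
  per_event$ef_pct <- ifelse(per_event$edd_mm > 0,
    (per_event$edd_mm^2 - per_event$esd_mm^2) / per_event$edd_mm^2 * 100,
    NA_real_)
  per_event$contraction_duration_s <-
    (events$trough_frame - events$start_frame) / fps
  per_event$shortening_speed_mm_s <-
    per_event$ca_mm / per_event$contraction_duration_s
  prev <- if (n == 0L) integer(0) else c(NA_integer_, seq_len(n - 1L))
  per_event$relaxation_duration_s <-
    (events$start_frame - events$trough_frame[prev]) / fps
  per_event$filling_speed_mm_s <-
    (per_event$edd_mm - per_event$esd_mm[prev]) / per_event$relaxation_duration_s
  per_event$refill_pct <-
    (per_event$edd_mm - per_event$esd_mm[prev]) / per_event$ca_mm[prev] * 100

  cf <- NA_real_
  if (n >= 2L && !is.na(fps)) {
    anchor <- if (cf_mode == "trough") events$trough_frame else events$start_frame
    cf <- 60 * fps / mean(diff(anchor))          # min^-1
  }
  mean_ef <- if (n >= 1L) mean(per_event$ef_pct, na.rm = TRUE) else NA_real_
  fpf <- if (fpf_mode == "per_event") mean_ef * cf else {
    medd <- mean(per_event$edd_mm); mesd <- mean(per_event$esd_mm)
    if (n >= 1L && medd > 0) (medd^2 - mesd^2) / medd^2 * 100 * cf else NA_real_
  }

  stat_cols <- c("edd_mm", "esd_mm", "ca_mm", "ef_pct",
                 "contraction_duration_s", "shortening_speed_mm_s",
                 "relaxation_duration_s", "filling_speed_mm_s", "refill_pct")
  stats <- if (n >= 1L) data.frame(
    parameter = stat_cols,
    mean = vapply(stat_cols, function(cn) mean(per_event[[cn]], na.rm = TRUE),
                  numeric(1L)),
    sd = vapply(stat_cols, function(cn) stats::sd(per_event[[cn]], na.rm = TRUE),
                numeric(1L)),
    row.names = NULL)
  else data.frame(parameter = character(0), mean = numeric(0), sd = numeric(0))

  structure(list(
    n_contractions = n,
    cf_per_min = cf,
    fpf_pct_per_min = fpf,
    mean_ef_pct = mean_ef,
    peak_mm = max(sm, na.rm = TRUE) * k,
    nadir_mm = min(sm, na.rm = TRUE) * k,
    per_event = per_event,
    stats = stats,
    units = units, fps = fps, mm_per_px = if (units == "mm") k else NA_real_,
    fpf_mode = fpf_mode, cf_mode = cf_mode),
    class = "contractile_summary")
}

#' @export
print.contractile_summary <- function(x, digits = 2, ...) {
  u <- x$units
  cat("Contractile summary (", x$n_contractions, " contraction(s))\n", sep = "")
  fmt <- function(v) ifelse(is.na(v), "-", format(round(v, digits), nsmall = digits))
  cat("  Contraction frequency (CF): ", fmt(x$cf_per_min), " min^-1\n", sep = "")
  cat("  Fractional pump flow (FPF): ", fmt(x$fpf_pct_per_min), " % min^-1\n",
      sep = "")
  cat("  Peak / nadir: ", fmt(x$peak_mm), " / ", fmt(x$nadir_mm), " ", u, "\n",
      sep = "")
  if (x$n_contractions >= 1L) {
    s <- x$stats
    lab <- c(edd_mm = paste0("EDD (", u, ")"), esd_mm = paste0("ESD (", u, ")"),
             ca_mm = paste0("CA (", u, ")"), ef_pct = "EF (%)",
             contraction_duration_s = "Contraction duration (s)",
             shortening_speed_mm_s = paste0("Shortening speed (", u, "/s)"),
             relaxation_duration_s = "Relaxation duration (s)",
             filling_speed_mm_s = paste0("Filling speed (", u, "/s)"),
             refill_pct = "Percent re-filling (%)")
    for (i in seq_len(nrow(s)))
      cat("  ", lab[[s$parameter[i]]], ": ", fmt(s$mean[i]), " +/- ",
          fmt(s$sd[i]), "\n", sep = "")
  }
  invisible(x)
}

#' Combine per-section summaries into one long table
#'
#' One row per (section, event) with all per-event metrics, ready for
#' amplitude-vs-duration and amplitude-over-time plots; sections with zero
#' events contribute one row with \code{event = NA} and missing metrics so
#' no section silently disappears.
#'
#' @param summaries list of \code{contractile_summary}, one per section
#'   (names or list index used as section id).
#' @return A long-format data.frame keyed by \code{section} and \code{event}.
#' @export
compare_sections <- function(summaries) {
  ids <- names(summaries)
  if (is.null(ids)) ids <- as.character(seq_along(summaries))
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    if (is.null(s) || s$n_contractions == 0L) {
      out <- summarize_template()
      out$section <- ids[i]
      out$n_contractions <- if (is.null(s)) NA_integer_ else 0L
      return(out)
    }
    cbind(section = ids[i], n_contractions = s$n_contractions,
          cf_per_min = s$cf_per_min, s$per_event)
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    template <- summarize_template()
    missing_cols <- setdiff(names(template), names(r))
    for (cn in missing_cols) r[[cn]] <- template[[cn]][0][1L]
    r[names(template)]
  }))
  rownames(out) <- NULL
  out
}

summarize_template <- function() {
  data.frame(section = NA_character_, n_contractions = NA_integer_,
             cf_per_min = NA_real_, event = NA_integer_,
             start_frame = NA_integer_, trough_frame = NA_integer_,
             end_frame = NA_integer_, edd_mm = NA_real_, esd_mm = NA_real_,
             ca_mm = NA_real_, ef_pct = NA_real_,
             contraction_duration_s = NA_real_,
             shortening_speed_mm_s = NA_real_,
             relaxation_duration_s = NA_real_, filling_speed_mm_s = NA_real_,
             refill_pct = NA_real_)
}
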