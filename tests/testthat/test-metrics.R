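# fps = 100 makes the reference durations (2.75 s contraction, 3.61 s
# relaxation) exact integer frame counts
mk_events <- function(edd_px, esd_px, starts, troughs, ends = troughs + 50L) {
  data.frame(start_frame = as.integer(starts),
             trough_frame = as.integer(troughs),
             end_frame = as.integer(ends),
             edd_px = rep_len(edd_px, length(starts)),
             esd_px = rep_len(esd_px, length(starts)),
             amplitude_px = rep_len(edd_px - esd_px, length(starts)),
             truncated = FALSE)
}

test_that("contractile parameters follow their defining formulas", {
  # EDD 0.20 mm, ESD 0.08 mm at 0.01 mm/px; contraction 275 frames = 2.75 s,
  # relaxation 361 frames = 3.61 s at 100 fps
  ev <- mk_events(20, 8,
                  starts = c(1000L, 1636L), troughs = c(1275L, 1911L))
  series <- rep(15, 2100)
  su <- summarize_events(ev, series, calib = calibration(0.01), fps = 100)
  expect_equal(su$per_event$ca_mm, c(0.12, 0.12))            # CA = EDD - ESD
  expect_equal(su$per_event$ef_pct,
               rep((0.2^2 - 0.08^2) / 0.2^2 * 100, 2))       # EF = 84%
  expect_equal(su$per_event$contraction_duration_s, c(2.75, 2.75))
  expect_equal(round(su$per_event$shortening_speed_mm_s, 2), c(0.04, 0.04))
  expect_equal(su$per_event$relaxation_duration_s[2], 3.61)
  expect_equal(round(su$per_event$filling_speed_mm_s[2], 2), 0.03)
  expect_equal(su$per_event$refill_pct[2], 100)  # full re-expansion
  # predecessor-dependent fields absent (not zero) for the first event
  expect_true(is.na(su$per_event$relaxation_duration_s[1]))
  expect_true(is.na(su$per_event$filling_speed_mm_s[1]))
  expect_true(is.na(su$per_event$refill_pct[1]))
})

test_that("contraction frequency is the reciprocal mean trough interval", {
  # uniform 6.3636 s spacing -> CF = 60 / 6.3636 = 9.4286 per minute
  fps <- 22
  spacing <- 140L                                 # 140 / 22 = 6.3636 s
  troughs <- 100L + spacing * (0:3)
  ev <- mk_events(15, 6, starts = troughs - 60L, troughs = troughs)
  su <- summarize_events(ev, rep(10, 700), fps = fps)
  expect_equal(su$cf_per_min, 60 / (spacing / fps), tolerance = 1e-12)
  expect_equal(su$cf_per_min, 9.4286, tolerance = 1e-4)
  # EDD-to-EDD mode agrees here because starts are equally shifted
  su2 <- summarize_events(ev, rep(10, 700), fps = fps, cf_mode = "start")
  expect_equal(su2$cf_per_min, su$cf_per_min)
})

test_that("FPF is mean per-event EF times CF, by construction", {
  set.seed(13)
  edd <- runif(4, 12, 18); esd <- runif(4, 4, 8)
  troughs <- c(100L, 230L, 380L, 500L)
  ev <- data.frame(start_frame = troughs - 50L, trough_frame = troughs,
                   end_frame = troughs + 40L, edd_px = edd, esd_px = esd,
                   amplitude_px = edd - esd, truncated = FALSE)
  su <- summarize_events(ev, rep(10, 600), fps = 22)
  expect_equal(su$fpf_pct_per_min, mean(su$per_event$ef_pct) * su$cf_per_min)
  # EF identity: EF = (1 - (ESD/EDD)^2) * 100
  expect_equal(su$per_event$ef_pct, (1 - (esd / edd)^2) * 100)
  # aggregate mode uses EF of the mean diameters instead
  su_agg <- summarize_events(ev, rep(10, 600), fps = 22,
                             fpf_mode = "aggregate")
  expect_equal(su_agg$fpf_pct_per_min,
               (mean(edd)^2 - mean(esd)^2) / mean(edd)^2 * 100 * su$cf_per_min)
})

test_that("degenerate summaries stay honest: limits, absences, flags", {
  # ESD = EDD: the no-contraction limit
  ev <- mk_events(10, 10, starts = c(10L, 150L), troughs = c(60L, 200L))
  su <- summarize_events(ev, rep(10, 300), fps = 22)
  expect_equal(su$per_event$ca_mm, c(0, 0))
  expect_equal(su$per_event$ef_pct, c(0, 0))
  # single event: CF and FPF absent, not zero
  su1 <- summarize_events(ev[1L, ], rep(10, 300), fps = 22)
  expect_true(is.na(su1$cf_per_min))
  expect_true(is.na(su1$fpf_pct_per_min))
  expect_equal(su1$n_contractions, 1L)
  # EDD = 0: EF undefined, flagged NA
  ev0 <- mk_events(0, 0, starts = 10L, troughs = 60L)
  su0 <- summarize_events(ev0, rep(10, 300), fps = 22)
  expect_true(is.na(su0$per_event$ef_pct))
  # zero events: summary exists with peak/nadir from the series
  sue <- summarize_events(ev[0L, ], c(3, 9, 6), fps = 22)
  expect_equal(sue$n_contractions, 0L)
  expect_equal(sue$peak_mm, 9)
  expect_equal(sue$nadir_mm, 3)
})

test_that("linear quantities commute with unit conversion", {
  ev <- mk_events(16, 7, starts = c(20L, 160L), troughs = c(80L, 220L))
  in_px <- summarize_events(ev, rep(10, 400), fps = 22)
  in_mm <- summarize_events(ev, rep(10, 400), fps = 22,
                            calib = calibration(0.0137))
  for (col in c("edd_mm", "esd_mm", "ca_mm", "shortening_speed_mm_s",
                "filling_speed_mm_s"))
    expect_equal(in_mm$per_event[[col]], in_px$per_event[[col]] * 0.0137)
  # EF and percent re-filling are unit-free
  expect_equal(in_mm$per_event$ef_pct, in_px$per_event$ef_pct)
  expect_equal(in_mm$per_event$refill_pct, in_px$per_event$refill_pct)
  expect_equal(in_px$units, "px")
  expect_equal(in_mm$units, "mm")
})

test_that("section comparison keeps empty sections visible", {
  ev <- mk_events(15, 6, starts = c(20L, 160L), troughs = c(80L, 220L))
  s_two <- summarize_events(ev, rep(10, 400), fps = 22)
  s_none <- summarize_events(ev[0L, ], rep(10, 400), fps = 22)
  tab <- compare_sections(list(a = s_two, b = s_none, c = NULL))
  expect_equal(nrow(tab), 4L)                     # 2 events + 2 placeholders
  expect_equal(sum(tab$section == "a"), 2L)
  expect_equal(tab$n_contractions[tab$section == "b"], 0L)
  expect_true(is.na(tab$event[tab$section == "b"]))
  expect_true(is.na(tab$n_contractions[tab$section == "c"]))
})
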