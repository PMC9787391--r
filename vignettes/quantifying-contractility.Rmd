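---
title: "Quantifying lymphatic contractile function from stereomicroscope video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lymphatic contractile function from stereomicroscope video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphpulse)
```

## The measurement problem

Collecting lymphatic vessels pump lymph by spontaneous phasic contractions.
Under a stereomicroscope at low magnification, a mesenteric lymphatic filled
with blue dye appears as a dark band — the dye absorbs the wavelengths a
colour camera records as red — on a brighter mesentery, over a field of view
of roughly a centimetre. `lymphpulse` turns such a recording into
quantitative contractile physiology: the diameter of the vessel at every
pixel row along its length in every frame (a kymograph), the contraction
events in the mean-diameter trace, and the standard contractile parameters,
both for the whole region of interest and for fixed-length sections along
the vessel.

The pipeline is:

1. **ROI extraction** (`extract_roi`): a rotated rectangle isolating one
   vessel segment is resampled (bilinear, per channel) so the vessel runs
   vertically. The textual ROI form `cx,cy,length,width,angle` is the exact
   record of a selection.
2. **Segmentation** (`segment_video`): one red-channel threshold for the
   whole video; pixels strictly below it are vessel. The default threshold
   is the mean of per-frame Otsu splits over six equally spaced frames.
   8-connected components smaller than 10 px are removed as artifacts.
   Pixels within 5 px (euclidean, inclusive) of a saturated pixel — glare
   that whites out all three channels — are excluded from measurement.
3. **Width profiling** (`build_profile`): vessel width per pixel row per
   frame, as a pixel count. Rows whose vessel pixels touch the exclusion
   zone are missing, not zero; empty rows are zero, not missing.
4. **Event detection** (`analyze_contractions`): the mean-width trace is
   smoothed (20-frame centred window); troughs are frames preceded by 10
   non-increasing and followed by 10 non-decreasing differences (each run
   with at least one strict step); each trough is expanded forwards and
   backwards to where the curve flattens or reverses. Events with amplitude
   below 1 px or spanning more than 110 frames are rejected.
5. **Metrics** (`summarize_events`): per event, end-diastolic and
   end-systolic diameter (EDD, ESD), contraction amplitude CA = EDD − ESD,
   ejection fraction EF = (EDD² − ESD²)/EDD² × 100, durations and speeds;
   per recording, contraction frequency CF = 1/mean(trough-to-trough
   interval), fractional pump flow FPF = mean(EF) × CF, and the overall
   peak/nadir.
6. **Sectioning** (`per_section_pipeline`): steps 4–5 repeated
   independently on 30-px sections along the vessel, which is where
   spatially heterogeneous contractility becomes visible.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `threshold` | automatic | intensity | contrast varies across preparations; an absolute default fails |
| `n_sample_frames` | 6 | frames | threshold stability across the video |
| `min_component_px` | 10 | px | specks smaller than this are artifacts, not vessels (strictly-below removal) |
| `saturation_fraction` | 0.99 | — | "saturated" means ≥ 99 % of the camera range in all three channels |
| `exclusion_radius_px` | 5 | px | glare corrupts edges beyond the saturated core |
| `window_frames` | 20 | frames | ~0.9 s at 22 FPS; shorter than a contraction limb, longer than flicker |
| `run_frames` | 10 | frames | ~0.45 s of sustained decrease/increase flanking a genuine trough |
| `min_amplitude_px` | 1 | px | sub-pixel "contractions" are quantization noise |
| `max_duration_frames` | 110 | frames | 5 s at 22 FPS; longer cycles are not viable single contractions |
| `section_len_px` | 30 | px | 0.41 mm at 13.7 µm/px: averages single-pixel noise, resolves along-vessel heterogeneity |
| `mm_per_px` | none | mm | set per setup via `calibrate_from_points()`; 13.7 µm/px is a typical documented value, never a built-in default |

All of these are recorded in the one-line reproducibility log
(`repro_log_line`) and the saved run config, from which a run is exactly
repeatable.

## Design choices where the design was open

**Threshold criterion.** The automatic per-frame split is the Otsu
between-class-variance maximizer on the red-channel histogram, computed
exhaustively; when several cutoffs tie (an empty histogram gap), the
midpoint of the maximizing plateau is used. Otsu is deterministic, standard,
and behaves like two-class k-means on well-separated histograms.

**Connectivity.** Components use 8-connectivity so diagonal vessel edges do
not fragment into removable fragments.

**Width definition.** Width is the count of vessel pixels in a row, not the
outer-edge span. The two differ only for vessels with interior holes, and
the component filter has already removed stray specks that would corrupt
counts.

**Smoothing.** Two window filters are provided. The default is a centred
moving average. The alternative (`method = "kmeans"`) splits each 20-frame
window into two clusters by exact 1-D 2-means and replaces the centre value
by its cluster centroid; it preserves sharp level changes, but on the
roughly linear limbs of a real contraction its cluster assignment flips
between adjacent windows, injecting non-monotone steps of a pixel or more
that defeat the run-based minima rule (and a lone spike is optimally its own
cluster, so it is not removed either). A monotone-preserving smoother is a
prerequisite for the detector, hence the moving-average default.

**Where diameters are read.** Detection runs on the smoothed trace, but a
centred moving average raises the trace at a trough by roughly the mean limb
slope times half the window (about 1 px under typical conditions), which
would systematically inflate ESD. By default the event boundaries are
therefore refined against the raw trace — the trough moves to the raw
minimum within half a window ("immediately after contraction", earliest tie),
the start to the raw maximum ("immediately before contraction", latest tie) —
and EDD/ESD, like the recording peak/nadir, are read from the measured
values. `measure = "smoothed"` reads everything from the filtered trace
instead.

**Plateau tolerance.** Integer-quantized widths plateau constantly, so the
10-frame runs flanking a trough accept zero differences as long as at least
one step is strict; `strict = TRUE` restores strict monotonicity. A flat
trough bottom is reported at its earliest frame, and event expansion first
skips the flat bottom before climbing.

**CF interval.** Contraction frequency uses trough-to-trough intervals;
`cf_mode = "start"` switches to EDD-to-EDD. FPF averages per-event ejection
fractions (`fpf_mode = "aggregate"` uses the EF of the mean diameters
instead).

**Sections.** The trailing short section is kept and flagged rather than
dropped, so users can decide.

**Missing data.** A frame is missing when more than half its positions are
excluded; interior gaps are bridged by linear interpolation before smoothing
and re-flagged afterwards. Exclusion is per whole pixel-row, since width is
a per-row scalar.

**Indices.** Written outputs (CSVs, the ROI text form) use 0-based frame and
position indices with position 0 at the image top, matching raster order;
in-memory R objects use R's native 1-based indexing.

## The synthetic test bed

Because ground truth is unobtainable for real vessels, every pipeline stage
is validated on synthetic recordings (`vessel_scene`, `render_scene`): a
vertical dark vessel whose width at position y and frame t is
`baseline(y) − amplitude(y)·pulse(t)`, rendered with sub-pixel coverage
shading at the edges, plus saturated glare discs and Gaussian sensor noise
on the red channel. The generator returns the analytic width matrix and the
pulse's event frames, so recovery can be checked exactly.

`preset_paper_like()` encodes the reference acquisition: 22 FPS, 30 s
(660 frames), diastolic diameter 15 px and end-systolic diameter 6 px
(about 205 µm and 82 µm at 13.7 µm/px), four contractions 140 frames apart
(CF 9.43 min⁻¹), a 60-frame (2.73 s) contraction limb, a 30-frame fast
refill followed by a diastolic plateau (physiological refilling is fast,
then slow — and only a trace that flattens well before the next contraction
is compatible with the 5-s event-duration cutoff), contraction amplitude
varying linearly from 6 to 12 px along the vessel, mild noise (SD 2
intensity levels) and one glare disc beside the vessel.

What the preset does *not* emulate: breathing or pulsation motion (the
threshold approach does not require stabilization), dye washout, focus
drift, non-vertical or curved vessels (handled upstream by the ROI), and
valve motion or flow. Passing tests therefore demonstrate the correctness
of the measurement chain, not robustness to every artifact of live imaging —
thresholds still deserve the visual confirmation views
(`render_confirmation_montage`, overlay video) on real data.

```{r pipeline, eval = FALSE}
scene <- preset_paper_like()
rendered <- render_scene(scene)
segs <- segment_video(rendered$clip)
profile <- build_profile(segs, fps = 22, calib = 0.0137)
analysis <- analyze_contractions(mean_width_series(profile),
                                 fps = 22, calib = 0.0137)
analysis
per_section_pipeline(profile)
```

## Numerical behaviour and known limitations

* **Half-pixel edge bias.** With anti-aliased edges, thresholding counts an
  edge pixel when its vessel coverage exceeds a threshold-dependent value
  near one half. A vessel whose true edges fall exactly on half-pixel
  boundaries is measured ±1 px depending on which side of the midpoint the
  threshold lands; diameters are accurate to about a pixel by construction,
  never better. Comparisons between conditions measured with the same
  settings are unaffected.
* **Degenerate inputs.** Constant-intensity videos have no contrast and
  raise an error rather than a meaningless threshold; single-frame inputs
  run the spatial pipeline but refuse time-domain analysis; a section that
  is excluded everywhere is reported absent, not as zero contractions.
* **Determinism.** Everything downstream of the generator is deterministic;
  the generator itself is bit-reproducible for a given seed. Re-running a
  saved config on the same input reproduces every CSV byte for byte.
* **Event edge cases.** Events at the series boundary are truncated and
  flagged; overlapping events cannot occur (troughs are separated by the
  run rule, expansions stop at flattening points and may at most share a
  boundary frame).
* **Physiology not measured.** Flow, valve position and wall shear are out
  of reach at this magnification; FPF inherits the assumption of a circular
  cross-section and competent valves.

## Problem sizes used in the tests

The bundled validation runs on the 660-frame, 150 x 40 px preset scene and
on 300-frame, 60 x 40 px variants — ROI-scale videos, which is what the
analysis operates on after extraction. These sizes were chosen to exercise
every code path (multiple sections, glare exclusion, noise) with exact
ground truth; the algorithms are linear in pixels x frames and run on
full-frame recordings unchanged.
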