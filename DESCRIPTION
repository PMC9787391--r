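Package: lymphpulse
Title: Quantify Lymphatic Vessel Contractile Function from Stereomicroscope Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures mesenteric lymphatic vessel contractile function from
    low-magnification stereomicroscope video of blue-dye-filled vessels.
    Segments the vessel in every frame by thresholding the red channel,
    measures vessel width at every pixel row along the vessel length (the
    kymograph), detects contraction events on the smoothed mean-width trace,
    and derives the standard contractile parameters (contraction frequency,
    end-diastolic and end-systolic diameter, contraction amplitude, ejection
    fraction, fractional pump flow, durations, speeds and percent re-filling)
    for the whole region of interest and for fixed-length sections along the
    vessel. Includes saturation-glare exclusion, a rotated region-of-interest
    extractor, overlay/preview rendering for manual verification, and a
    ground-truthed synthetic vessel video generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
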