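test_that("otsu threshold matches the exhaustive-search oracle", {
  # clean bimodal: half 10, half 200 -> every frame gives the same split
  v <- c(rep(10L, 50), rep(200L, 50))
  expect_equal(otsu_threshold(v), oracle_otsu(v))
  set.seed(11)
  for (i in 1:12) {
    lo <- sample(20:80, 1); hi <- sample(120:230, 1)
    vals <- as.integer(pmin(255, pmax(0, c(
      rnorm(sample(50:300, 1), lo, sample(3:15, 1)),
      rnorm(sample(50:300, 1), hi, sample(3:15, 1))))))
    expect_equal(otsu_threshold(vals), oracle_otsu(vals))
  }
  expect_true(is.na(otsu_threshold(rep(7L, 100))))
})

test_that("otsu agrees with EBImage's implementation on a noisy bimodal image", {
  set.seed(3)
  m <- matrix(as.integer(pmin(255, pmax(0, c(rnorm(200, 60, 10),
                                             rnorm(312, 190, 12))))), 32, 16)
  ours <- otsu_threshold(m)
  ref <- EBImage::otsu(EBImage::Image(m / 255), range = c(0, 1),
                       levels = 256) * 255
  expect_lt(abs(ours - ref), 2)
})

test_that("auto threshold averages per-frame splits over equally spaced frames", {
  # three frames engineered to have distinct, oracle-computable splits
  set.seed(4)
  mk <- function(lo, hi) {
    fr <- flat_frame(10, 10)
    fr[, , 1L] <- as.integer(c(rep(lo, 50), rep(hi, 50)))
    fr
  }
  frames <- list(mk(10, 200), mk(30, 150), mk(50, 250))
  clip <- video_clip(frames, fps = 1)
  expected <- mean(vapply(frames, function(f) oracle_otsu(f[, , 1L]), 1))
  expect_equal(auto_threshold(clip, 3), expected)
  # constant clip -> "no contrast"
  flat <- video_clip(list(flat_frame(5, 5), flat_frame(5, 5)), fps = 1)
  expect_error(auto_threshold(flat, 2), "no contrast")
})

test_that("components below 10 px are removed, 10 px kept (strict rule)", {
  fr <- flat_frame(30, 30)
  fr[2:4, 2:4, 1L] <- 0L          # 9-px blob
  fr[10:14, 10:11, 1L] <- 0L      # 10-px blob
  seg <- segment_frame(fr, threshold_config(threshold = 100))
  expect_false(any(seg$vessel_mask[2:4, 2:4]))
  expect_true(all(seg$vessel_mask[10:14, 10:11]))
  expect_equal(sum(seg$vessel_mask), 10L)
})

test_that("diagonally-touching pixels form one component (8-connectivity)", {
  fr <- flat_frame(20, 20)
  diag_px <- cbind(3:12, 3:12)
  fr[, , 1L][diag_px] <- 0L       # 10-px diagonal chain
  seg <- segment_frame(fr, threshold_config(threshold = 100,
                                            min_component_px = 10))
  expect_equal(sum(seg$vessel_mask), 10L)   # survives the 10-px filter intact
})

test_that("component filter equals the brute-force flood-fill oracle", {
  set.seed(5)
  for (i in 1:20) {
    h <- sample(4:32, 1); w <- sample(4:32, 1)
    mask <- matrix(stats::runif(h * w) < stats::runif(1, 0.25, 0.7), h, w)
    min_px <- sample(1:12, 1)
    got <- lymphpulse:::filter_small_components(mask, min_px)
    expect_identical(got, oracle_filter_components(mask, min_px) & TRUE)
  }
})

test_that("saturation exclusion equals brute-force euclidean distance", {
  fr <- flat_frame(40, 40)
  fr[20, 20, ] <- 255L
  seg <- segment_frame(fr, threshold_config(threshold = 100))
  expect_identical(seg$exclusion_mask, oracle_exclusion(fr))
  # distance exactly 5 is excluded (inclusive boundary)
  expect_true(seg$exclusion_mask[20, 25])
  expect_true(seg$exclusion_mask[23, 24])   # 3-4-5 triangle
  expect_false(seg$exclusion_mask[20, 26])
  set.seed(6)
  for (i in 1:6) {
    fr <- flat_frame(24, 24)
    nsat <- sample(0:3, 1)
    for (k in seq_len(nsat)) fr[sample(24, 1), sample(24, 1), ] <- 255L
    seg <- segment_frame(fr, threshold_config(threshold = 100))
    expect_identical(seg$exclusion_mask, oracle_exclusion(fr))
  }
})

test_that("raising the threshold never shrinks the pre-filter vessel set", {
  set.seed(7)
  fr <- flat_frame(20, 20)
  fr[, , 1L] <- as.integer(sample(0:255, 400, TRUE))
  prev <- matrix(FALSE, 20, 20)
  for (t in seq(10, 250, by = 40)) {
    cur <- fr[, , 1L] < t
    expect_true(all(cur | !prev))   # prev subset of cur
    prev <- cur
  }
})

test_that("segmentation is deterministic and recovers synthetic widths", {
  sc <- small_scene(noise_sd = 0)
  r <- render_scene(sc)
  segs <- segment_video(r$clip, quiet = TRUE)
  # identical frames -> identical masks
  expect_identical(segs[[1L]]$vessel_mask,
                   segment_video(r$clip, quiet = TRUE)[[1L]]$vessel_mask)
  # noise-free widths within +/- 2 px of analytic ground truth at every row
  prof <- build_profile(segs, fps = 22)
  err <- abs(prof$widths - r$truth_widths)
  expect_lt(max(err, na.rm = TRUE), 2 + 1e-9)
  # a threshold at the intensity floor yields empty masks
  seg0 <- segment_frame(r$clip$frames[[1L]], threshold_config(threshold = 1))
  expect_false(any(seg0$vessel_mask))
})

test_that("confirmation montage clamps its tile count to the frame count", {
  sc <- small_scene(noise_sd = 0)
  clip <- render_scene(sc)$clip
  clip <- video_clip(clip$frames[1:6], fps = 22)
  segs <- segment_video(clip, quiet = TRUE)
  p <- withr::local_tempfile(fileext = ".png")
  render_confirmation_montage(clip, segs, 6, p)
  img <- png::readPNG(p)
  expect_equal(ncol(img), 6 * clip$width + 5 * 2)  # 6 tiles + 2-px gaps
  one <- video_clip(clip$frames[1L], fps = 22)
  render_confirmation_montage(one, segs[1L], 6, p)
  img <- png::readPNG(p)
  expect_equal(ncol(img), clip$width)              # clamped to 1 tile
})
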