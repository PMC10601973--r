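test_that("binocular merging averages eyes and falls back to the valid one", {
  s <- gaze_stream(data.frame(timestamp_ms = c(0, 8, 16),
                              left_x = c(100, NA, NA),
                              left_y = c(200, NA, NA),
                              right_x = c(110, 50, NA),
                              right_y = c(210, 60, NA)),
                   "p", "t")
  m <- merge_binocular(s)
  expect_equal(m$x, c(105, 50, NA))
  expect_equal(m$y, c(205, 60, NA))
  expect_equal(nrow(m), 3)  # missing samples keep their slot
})

test_that("stable gaze yields one fixation; alternating jumps yield none", {
  pts <- const_points(13, 500, 500)
  fx <- detect_fixations(pts)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$x, 500)
  expect_equal(fx$y, 500)
  expect_equal(fx$duration_ms, 100, tolerance = 1e-9)
  expect_equal(fx$n_samples, 13)

  alt <- const_points(40, 0, 0)
  alt$x <- rep(c(100, 600), 20); alt$y <- rep(c(100, 600), 20)
  expect_equal(nrow(detect_fixations(alt)), 0)
})

test_that("two jittered clusters separated by a jump give two fixations", {
  withr::local_seed(42)
  c1 <- const_points(12, 300, 300)
  c1$x <- c1$x + runif(12, -5, 5); c1$y <- c1$y + runif(12, -5, 5)
  jump <- const_points(1, 600, 420, t0 = 12 * 1000 / 120)
  c2 <- const_points(12, 900, 540, t0 = 13 * 1000 / 120)
  c2$x <- c2$x + runif(12, -5, 5); c2$y <- c2$y + runif(12, -5, 5)
  fx <- detect_fixations(rbind(c1, jump, c2))
  expect_equal(nrow(fx), 2)
  expect_lt(abs(fx$x[1] - 300), 5); expect_lt(abs(fx$y[1] - 300), 5)
  expect_lt(abs(fx$x[2] - 900), 5); expect_lt(abs(fx$y[2] - 540), 5)
})

test_that("boundary probes: inclusive 50-ms duration, exclusive 25-px step", {
  # 7 samples at exactly 125 Hz-style spacing spanning exactly 50.0 ms
  pts <- data.frame(timestamp_ms = seq(0, 50, length.out = 7), x = 400, y = 400)
  expect_equal(nrow(detect_fixations(pts)), 1)  # >= is inclusive
  pts_short <- data.frame(timestamp_ms = seq(0, 49.9, length.out = 7),
                          x = 400, y = 400)
  expect_equal(nrow(detect_fixations(pts_short)), 0)

  # consecutive steps of exactly 25 px break the run; 24.99 px does not
  step25 <- const_points(13, 0, 0)
  step25$x <- seq(0, by = 25, length.out = 13)
  expect_equal(nrow(detect_fixations(step25)), 0)
  step24 <- const_points(13, 0, 0)
  step24$x <- seq(0, by = 24.99, length.out = 13)
  expect_equal(nrow(detect_fixations(step24)), 1)
})

test_that("missing samples are bridged, but gaps beyond max_gap split runs", {
  a <- const_points(7, 100, 100)
  gap <- data.frame(timestamp_ms = 7 * 1000 / 120 + c(0, 8, 16), x = NA, y = NA)
  b <- const_points(7, 104, 100, t0 = 7 * 1000 / 120 + 25)
  fx <- detect_fixations(rbind(a, gap, b))
  expect_equal(nrow(fx), 1)  # 25-ms non-missing gap is bridged
  expect_equal(fx$n_samples, 14)

  far <- const_points(7, 104, 100, t0 = 7 * 1000 / 120 + 100)
  fx2 <- detect_fixations(rbind(a, far))  # 100-ms gap > 75 splits
  expect_equal(nrow(fx2), 2)
})

test_that("detection matches the exhaustive maximal-run oracle on random streams", {
  withr::local_seed(314)
  params <- fixation_params()
  for (rep in 1:60) {
    pts <- random_points(sample(50:400, 1),
                         missing_prob = runif(1, 0, 0.25),
                         jump_prob = runif(1, 0, 0.15),
                         jitter = runif(1, 2, 12))
    got <- detect_fixations(pts, params)
    want <- oracle_fixations(pts)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start_ms, want$start_ms)
      expect_equal(got$end_ms, want$end_ms)
      expect_equal(got$x, want$x)
      expect_equal(got$y, want$y)
      expect_equal(got$n_samples, want$n_samples)
    }
  }
})

test_that("threshold monotonicity and translation invariance hold", {
  withr::local_seed(99)
  for (rep in 1:20) {
    pts <- random_points(250)
    f25 <- detect_fixations(pts, fixation_params(dispersion_px = 25))
    f40 <- detect_fixations(pts, fixation_params(dispersion_px = 40))
    expect_gte(sum(f40$n_samples), sum(f25$n_samples))
    d80 <- detect_fixations(pts, fixation_params(min_duration_ms = 80))
    expect_lte(nrow(d80), nrow(f25))
    # every non-missing sample is covered by at most one fixation
    covered <- 0
    for (i in seq_len(nrow(f25))) {
      covered <- covered + sum(pts$timestamp_ms >= f25$start_ms[i] &
                                 pts$timestamp_ms <= f25$end_ms[i] &
                                 !is.na(pts$x))
    }
    expect_equal(covered, sum(f25$n_samples))
    shifted <- pts
    shifted$x <- pts$x + 137.5; shifted$y <- pts$y - 42.25
    fs <- detect_fixations(shifted, fixation_params())
    expect_equal(fs$start_ms, f25$start_ms)
    expect_equal(fs$x, f25$x + 137.5)
    expect_equal(fs$y, f25$y - 42.25)
  }
})

test_that("screen-to-image mapping inverts the display geometry", {
  p <- data.frame(x = 10, y = 20)
  expect_equal(map_screen_to_image(p)[, c("x", "y")], p)
  expect_equal(map_screen_to_image(data.frame(x = 100, y = 50), scale = 2),
               data.frame(x = 50, y = 25))
  withr::local_seed(5)
  pts <- data.frame(x = runif(200, -500, 2500), y = runif(200, -500, 1500))
  sc <- 1.73; ox <- 123.4; oy <- -77.1
  img <- map_screen_to_image(pts, sc, ox, oy)
  back <- data.frame(x = img$x * sc + ox, y = img$y * sc + oy)
  expect_lt(max(abs(back$x - pts$x), abs(back$y - pts$y)), 1e-9)
  # out-of-image points are flagged, not clamped
  flagged <- map_screen_to_image(data.frame(x = c(-1, 5), y = c(5, 5)),
                                 image_width = 10, image_height = 10)
  expect_equal(flagged$in_image, c(FALSE, TRUE))
  expect_equal(flagged$x, c(-1, 5))
  expect_error(map_screen_to_image(p, scale = 0), "positive")
})
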