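small_cfg <- function(seed = 1, p_fix = 0.7, p_rec = 0.5, fp_rate = 1,
                      n_participants = 3, ...) {
  simulation_config(seed = seed, groups = list(
    list(label = "g", n_participants = n_participants,
         p_fixate_polyp = p_fix, p_recognize_given_fixation = p_rec,
         false_mark_rate = fp_rate)),
    n_positive_images = 4, n_polyps = 5, n_negative_images = 1,
    viewing_duration_ms = 4000, ...)
}

test_that("degenerate probabilities give all-correct and all-gaze-error studies", {
  d1 <- withr::local_tempdir()
  s1 <- simulate_study(small_cfg(p_fix = 1, p_rec = 1, missing_rate = 0), d1,
                       write_gaze = FALSE)
  r1 <- run_pipeline(s1, heatmaps = FALSE)
  expect_true(all(r1$outcomes$outcome == "CORRECT"))

  d2 <- withr::local_tempdir()
  s2 <- simulate_study(small_cfg(p_fix = 0, fp_rate = 0), d2, write_gaze = FALSE)
  r2 <- run_pipeline(s2, heatmaps = FALSE)
  expect_true(all(r2$outcomes$outcome == "GAZE_ERROR"))
  expect_equal(nrow(s2$marks), 0)
})

test_that("the same seed reproduces byte-identical study files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(small_cfg(seed = 42), d1)
  simulate_study(small_cfg(seed = 42), d2)
  rel <- c("rois.tsv", "marks.tsv", "labels.tsv", "manifest.yaml",
           file.path("gaze", list.files(file.path(d1, "gaze"))))
  for (f in rel) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("adding a participant leaves existing participants' data untouched", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(small_cfg(seed = 9, n_participants = 2), d1)
  simulate_study(small_cfg(seed = 9, n_participants = 3), d2)
  for (f in file.path("gaze", list.files(file.path(d1, "gaze")))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the study-shape preset matches the experimental design", {
  d <- withr::local_tempdir()
  study <- simulate_study(paper_shape_config(seed = 2), d, write_gaze = FALSE)
  expect_equal(nrow(study$rois), 25)
  expect_equal(length(unique(study$rois$image_id)), 20)
  expect_equal(length(study$manifest$negative_images), 5)
  expect_equal(length(unique(study$manifest$trials$participant_id)), 11)
  expect_equal(nrow(study$labels), 11 * 25)  # 275 encounter slots
  groups <- unique(study$manifest$trials[c("participant_id", "group")])
  expect_equal(as.integer(table(groups$group)[c("trainee", "student")]),
               c(7, 4))
  # streams are 12 s at 120 Hz
  s <- study$streams[[1]]
  expect_equal(nrow(s$samples), 1440)
  expect_equal(s$nominal_rate, 120)
})

test_that("noise-free simulation agrees exactly with ground-truth labels", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(seed = 5, missing_rate = 0, jitter_sigma = 1e-6,
                   binocular_disparity_sigma = 0)
  study <- simulate_study(cfg, d, write_gaze = FALSE)
  res <- run_pipeline(study, heatmaps = FALSE)
  agr <- label_agreement(res$outcomes, study$labels)
  expect_equal(agr$agreement, 1)
})

test_that("planted fixations survive detection at default parameters", {
  d <- withr::local_tempdir()
  study <- simulate_study(small_cfg(seed = 13, p_fix = 1), d,
                          write_gaze = FALSE)
  params <- fixation_params()
  for (key in names(study$streams)[1:8]) {
    stream <- study$streams[[key]]
    fx <- detect_fixations(merge_binocular(stream), params)
    img <- study$manifest$trials$image_id[
      paste0(study$manifest$trials$participant_id, "_",
             study$manifest$trials$trial_id) == key]
    rois_img <- study$rois[study$rois$image_id == img, , drop = FALSE]
    for (i in seq_len(nrow(rois_img))) {
      expect_true(any(point_in_roi(fx$x, fx$y, rois_img[i, ])),
                  label = paste("planted fixation found in", key))
    }
  }
})

test_that("outcome mix over many encounters matches the generative expectation", {
  # p_fixate 0.7, p_recognize 0.5 => CORRECT 0.35, COGNITIVE 0.35, GAZE 0.30
  d <- withr::local_tempdir()
  cfg <- simulation_config(seed = 31, groups = list(
    list(label = "g", n_participants = 24, p_fixate_polyp = 0.7,
         p_recognize_given_fixation = 0.5, false_mark_rate = 0)),
    n_positive_images = 10, n_polyps = 12, n_negative_images = 0,
    viewing_duration_ms = 2000)
  study <- simulate_study(cfg, d, write_gaze = FALSE)
  n <- nrow(study$labels)
  expect_gte(n, 250)
  mix <- prop.table(table(factor(study$labels$intended_outcome,
                                 c("CORRECT", "GAZE_ERROR",
                                   "COGNITIVE_ERROR"))))
  want <- c(CORRECT = 0.35, GAZE_ERROR = 0.30, COGNITIVE_ERROR = 0.35)
  for (lvl in names(want)) {
    se <- sqrt(want[[lvl]] * (1 - want[[lvl]]) / n)
    expect_lt(abs(mix[[lvl]] - want[[lvl]]), 3 * se)
  }
})

test_that("a too-small ROI for the configured jitter is rejected with advice", {
  cfg <- small_cfg(jitter_sigma = 50)
  rois <- data.frame(image_id = "img01", polyp_id = "p1", x_min = 0,
                     y_min = 0, x_max = 80, y_max = 80)
  expect_error(
    simulate_trial(cfg, cfg$groups[[1]], rois, "p", "t", "img01"),
    "jitter")
})
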