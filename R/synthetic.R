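# Synthetic study generator.
#
# Emulates the still-image experiment end to end: ground-truth polyp
# bounding boxes laid out over positive images, plus negative (polyp-free)
# images; per participant and image a 12-s scanpath sampled at 120 Hz built
# from planted fixations; annotation marks; and a ground-truth label per
# participant-polyp encounter. The generative model per polyp is two coin
# flips: with probability `p_fixate_polyp` a fixation is planted inside the
# box (otherwise the encounter is a gaze error); given a fixation, with
# probability `p_recognize_given_fixation` a mark is placed at its centre
# (correct detection), otherwise the encounter is a cognitive error.
# Remaining viewing time is filled with background fixations strictly
# outside every box, connected by 1-2-sample saccades that can never
# themselves form fixations.

#' Simulation configuration
#'
#' Defaults reproduce the study design the package targets: two cohorts
#' (7 trainees, 4 medical students) viewing 20 positive images containing 25
#' polyps plus 5 negative images at 1920 x 1080, 12 s of free viewing per
#' image sampled at 120 Hz. The cohorts' default detection probabilities are
#' back-calculated from the observed Phase-1 rates (trainee sensitivity
#' 49.1% with 27% of errors being gaze errors implies
#' `p_fixate ~ 0.863`, `p_recognize ~ 0.569`; students 35.0% and 44.6% imply
#' `0.710` and `0.493`), and the false-mark rates approximate the observed
#' PPVs.
#'
#' @param seed Root RNG seed. Per participant/trial sub-streams are derived
#'   by counter hashing, so adding a participant or group leaves every other
#'   participant's data untouched.
#' @param groups List of cohorts; each a list with `label`,
#'   `n_participants`, `p_fixate_polyp`, `p_recognize_given_fixation`,
#'   `false_mark_rate` (expected spurious marks per negative image).
#' @param n_positive_images,n_polyps,n_negative_images Image design;
#'   `n_polyps >= n_positive_images` (every positive image gets at least one
#'   polyp).
#' @param image_width,image_height Image dimensions, pixels.
#' @param viewing_duration_ms Free-viewing time per image (default 12,000).
#' @param sampling_rate Tracker rate in Hz (default 120).
#' @param fixation_duration_median_ms,fixation_duration_sigma Log-normal
#'   fixation duration model (median in ms and log-scale sigma); durations
#'   are floored at 80 ms so every planted fixation clears the 50-ms
#'   detection threshold.
#' @param jitter_sigma Isotropic within-fixation sample jitter, pixels. The
#'   jitter of each fixation is recentred to mean zero, so the sample mean
#'   sits exactly on the planned centre (and inside the box for planted
#'   fixations).
#' @param saccade_step Minimum distance between consecutive fixation
#'   centres, pixels (default 75 = 3x the 25-px dispersion threshold), so
#'   saccade transitions always break the dispersion rule.
#' @param missing_rate Per-eye, per-sample probability of signal loss.
#' @param binocular_disparity_sigma Per-sample eye disparity, pixels; the
#'   two eyes are offset antisymmetrically so their mean recovers the true
#'   gaze point.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              groups = list(
                                list(label = "trainee", n_participants = 7,
                                     p_fixate_polyp = 0.863,
                                     p_recognize_given_fixation = 0.569,
                                     false_mark_rate = 1.5),
                                list(label = "student", n_participants = 4,
                                     p_fixate_polyp = 0.710,
                                     p_recognize_given_fixation = 0.493,
                                     false_mark_rate = 3.2)),
                              n_positive_images = 20, n_polyps = 25,
                              n_negative_images = 5,
                              image_width = 1920, image_height = 1080,
                              viewing_duration_ms = 12000,
                              sampling_rate = 120,
                              fixation_duration_median_ms = 250,
                              fixation_duration_sigma = 0.4,
                              jitter_sigma = 4, saccade_step = 75,
                              missing_rate = 0.02,
                              binocular_disparity_sigma = 2) {
  cfg <- list(seed = as.integer(seed), groups = groups,
              n_positive_images = n_positive_images, n_polyps = n_polyps,
              n_negative_images = n_negative_images,
              image_width = image_width, image_height = image_height,
              viewing_duration_ms = viewing_duration_ms,
              sampling_rate = sampling_rate,
              fixation_duration_median_ms = fixation_duration_median_ms,
              fixation_duration_sigma = fixation_duration_sigma,
              jitter_sigma = jitter_sigma, saccade_step = saccade_step,
              missing_rate = missing_rate,
              binocular_disparity_sigma = binocular_disparity_sigma)
  for (g in cfg$groups) {
    p <- c(g$p_fixate_polyp, g$p_recognize_given_fixation)
    if (any(p < 0 | p > 1)) stop_("group '%s': probabilities must be in [0, 1]", g$label)
    if (g$false_mark_rate < 0) stop_("group '%s': false_mark_rate must be >= 0", g$label)
    if (g$n_participants < 1) stop_("group '%s': need >= 1 participant", g$label)
  }
  if (cfg$n_polyps < cfg$n_positive_images) {
    stop_("n_polyps must be >= n_positive_images (each positive image holds >= 1 polyp)")
  }
  pos <- c(cfg$viewing_duration_ms, cfg$sampling_rate,
           cfg$fixation_duration_median_ms, cfg$fixation_duration_sigma,
           cfg$jitter_sigma, cfg$saccade_step, cfg$image_width, cfg$image_height)
  if (any(pos <= 0)) stop_("durations, rates and dimensions must be positive")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_("missing_rate must be in [0, 1)")
  }
  structure(cfg, class = "simulation_config")
}

#' The bundled study-shape preset
#'
#' [simulation_config()] defaults plus any overrides: 2 groups (7 + 4
#' participants), 20 positive images with 25 polyps, 5 negatives — 275
#' participant-polyp encounter slots.
#'
#' @param seed Root RNG seed.
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
paper_shape_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, ...)
}

# Lay out non-overlapping ground-truth boxes over the positive images and
# attach lesion metadata with frequencies mimicking a subtle-polyp dataset.
simulate_rois <- function(cfg) {
  n_img <- cfg$n_positive_images
  n_extra <- cfg$n_polyps - n_img
  img_of_polyp <- c(seq_len(n_img),
                    if (n_extra > 0) {
                      sort(sample(seq_len(n_img), n_extra,
                                  replace = n_extra > n_img))
                    })
  margin <- 4 * cfg$jitter_sigma
  rois <- NULL
  for (img in seq_len(n_img)) {
    k <- sum(img_of_polyp == img)
    boxes <- NULL
    for (j in seq_len(k)) {
      lo <- max(60, 6 * cfg$jitter_sigma)
      for (attempt in seq_len(200)) {
        w <- stats::runif(1, lo, lo + 160)
        h <- stats::runif(1, lo, lo + 140)
        x0 <- stats::runif(1, 0, cfg$image_width - w)
        y0 <- stats::runif(1, 0, cfg$image_height - h)
        cand <- c(x0, y0, x0 + w, y0 + h)
        clear <- is.null(boxes) ||
          all(apply(boxes, 1, function(b) {
            cand[1] >= b[3] + margin || cand[3] <= b[1] - margin ||
              cand[2] >= b[4] + margin || cand[4] <= b[2] - margin
          }))
        if (clear) break
      }
      boxes <- rbind(boxes, cand)
    }
    rois <- rbind(rois, data.frame(
      image_id = sprintf("img%02d", img),
      polyp_id = sprintf("p%02d_%d", img, seq_len(k)),
      x_min = round(boxes[, 1], 1), y_min = round(boxes[, 2], 1),
      x_max = round(boxes[, 3], 1), y_max = round(boxes[, 4], 1)))
  }
  n <- nrow(rois)
  rois$size_mm <- round(pmin(40, stats::rlnorm(n, log(8), 0.6)), 1)
  rois$paris <- sample(c("IIa", "Is", "Ip"), n, replace = TRUE,
                       prob = c(0.72, 0.2, 0.08))
  rois$location <- sample(c("right", "left", "rectum"), n, replace = TRUE,
                          prob = c(0.76, 0.2, 0.04))
  rois$pathology <- sample(c("LGD adenoma", "SSL"), n, replace = TRUE,
                           prob = c(0.52, 0.48))
  validate_rois(rois, "simulated ROIs")
}

# Draw a fixation centre uniformly over the image, outside every ROI and at
# least `step` away from the previous centre (and optionally a next centre).
draw_background_center <- function(cfg, rois, prev = NULL, nxt = NULL) {
  for (attempt in seq_len(1000)) {
    p <- c(stats::runif(1, 0, cfg$image_width),
           stats::runif(1, 0, cfg$image_height))
    if (nrow(rois) > 0 && any(point_in_roi(p[1], p[2], rois))) next
    if (!is.null(prev) && sqrt(sum((p - prev)^2)) < cfg$saccade_step) next
    if (!is.null(nxt) && sqrt(sum((p - nxt)^2)) < cfg$saccade_step) next
    return(p)
  }
  stop_("could not place a background fixation; ROIs cover too much of the image")
}

#' Simulate one participant's trial on one image
#'
#' Implements the generative model described in [simulation_config()]. The
#' planted in-box fixations come first in the scanpath (separated by filler
#' background fixations whenever two boxes are closer than `saccade_step`),
#' then background fixations fill the remaining viewing time; the last one
#' may be truncated by the end of the trial.
#'
#' @param cfg A [simulation_config()].
#' @param group One element of `cfg$groups`.
#' @param rois ROI rows of this image (zero rows for a negative image).
#' @param participant_id,trial_id,image_id Identifiers.
#' @return List with `stream` (a `gaze_stream`), `marks` and `labels` (data
#'   frame `participant_id`, `polyp_id`, `intended_outcome`).
#' @export
simulate_trial <- function(cfg, group, rois, participant_id, trial_id,
                           image_id) {
  dt <- 1000 / cfg$sampling_rate
  n_total <- floor(cfg$viewing_duration_ms / dt)
  margin <- 2 * cfg$jitter_sigma
  if (nrow(rois) > 0 &&
      any(rois$x_max - rois$x_min <= 2 * margin |
          rois$y_max - rois$y_min <= 2 * margin)) {
    stop_("ROI too small to contain a jittered fixation; enlarge the ROI or reduce jitter_sigma")
  }

  # plan the fixation sequence: centres, durations, planted-polyp identity
  centers <- list(); planted_polyp <- character(0)
  labels <- NULL; marks_x <- numeric(0); marks_y <- numeric(0)
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    fixated <- stats::runif(1) < group$p_fixate_polyp
    recognized <- fixated &&
      stats::runif(1) < group$p_recognize_given_fixation
    if (fixated) {
      ctr <- c(stats::runif(1, roi$x_min + margin, roi$x_max - margin),
               stats::runif(1, roi$y_min + margin, roi$y_max - margin))
      prev <- if (length(centers)) centers[[length(centers)]]$p else NULL
      if (!is.null(prev) && sqrt(sum((ctr - prev)^2)) < cfg$saccade_step) {
        centers[[length(centers) + 1]] <-
          list(p = draw_background_center(cfg, rois, prev, ctr), polyp = NA)
      }
      centers[[length(centers) + 1]] <- list(p = ctr, polyp = roi$polyp_id)
      if (recognized) {
        marks_x <- c(marks_x, ctr[1]); marks_y <- c(marks_y, ctr[2])
      }
    }
    labels <- rbind(labels, data.frame(
      participant_id = participant_id, polyp_id = roi$polyp_id,
      intended_outcome = if (!fixated) "GAZE_ERROR"
                         else if (recognized) "CORRECT"
                         else "COGNITIVE_ERROR"))
  }

  # emit samples fixation by fixation until the viewing time is spent
  ts_all <- (seq_len(n_total) - 1) * dt
  px <- rep(NA_real_, n_total); py <- rep(NA_real_, n_total)
  pos <- 1L; idx <- 1L
  while (pos <= n_total) {
    if (idx <= length(centers)) {
      ctr <- centers[[idx]]$p
    } else {
      prev <- if (idx > 1) centers[[idx - 1]]$p else NULL
      ctr <- draw_background_center(cfg, rois, prev)
      centers[[idx]] <- list(p = ctr, polyp = NA)
    }
    dur <- max(80, stats::rlnorm(1, log(cfg$fixation_duration_median_ms),
                                 cfg$fixation_duration_sigma))
    n_f <- min(max(2L, as.integer(round(dur / dt))), n_total - pos + 1L)
    jit <- matrix(stats::rnorm(2 * n_f, 0, cfg$jitter_sigma), ncol = 2)
    jit <- sweep(jit, 2, colMeans(jit))  # sample mean exactly at the centre
    px[pos:(pos + n_f - 1L)] <- ctr[1] + jit[, 1]
    py[pos:(pos + n_f - 1L)] <- ctr[2] + jit[, 2]
    pos <- pos + n_f
    idx <- idx + 1L
    # saccade transition: 1-2 exact samples along the line to the next centre
    if (pos <= n_total) {
      prev <- ctr
      nxt <- if (idx <= length(centers)) centers[[idx]]$p else {
        centers[[idx]] <- list(p = draw_background_center(cfg, rois, prev),
                               polyp = NA)
        centers[[idx]]$p
      }
      d <- sqrt(sum((nxt - prev)^2))
      n_s <- if (d < 90) 1L else 2L
      n_s <- min(n_s, n_total - pos + 1L)
      fr <- seq_len(n_s) / (n_s + 1L)
      px[pos:(pos + n_s - 1L)] <- prev[1] + fr * (nxt[1] - prev[1])
      py[pos:(pos + n_s - 1L)] <- prev[2] + fr * (nxt[2] - prev[2])
      pos <- pos + n_s
    }
  }

  # binocular emission: antisymmetric disparity, independent per-eye dropout
  dx <- stats::rnorm(n_total, 0, cfg$binocular_disparity_sigma)
  dy <- stats::rnorm(n_total, 0, cfg$binocular_disparity_sigma)
  lost_l <- stats::runif(n_total) < cfg$missing_rate
  lost_r <- stats::runif(n_total) < cfg$missing_rate
  lx <- ifelse(lost_l, NA_real_, px + dx); ly <- ifelse(lost_l, NA_real_, py + dy)
  rx <- ifelse(lost_r, NA_real_, px - dx); ry <- ifelse(lost_r, NA_real_, py - dy)
  stream <- gaze_stream(
    data.frame(timestamp_ms = round(ts_all, 4),
               left_x = round(lx, 3), left_y = round(ly, 3),
               right_x = round(rx, 3), right_y = round(ry, 3)),
    participant_id = participant_id, trial_id = trial_id,
    nominal_rate = cfg$sampling_rate)

  # spurious marks on negative images
  if (nrow(rois) == 0 && group$false_mark_rate > 0) {
    n_fp <- stats::rpois(1, group$false_mark_rate)
    marks_x <- c(marks_x, stats::runif(n_fp, 0, cfg$image_width))
    marks_y <- c(marks_y, stats::runif(n_fp, 0, cfg$image_height))
  }
  marks <- if (length(marks_x) > 0) {
    data.frame(participant_id = participant_id, image_id = image_id,
               x = round(marks_x, 3), y = round(marks_y, 3),
               mark_time_ms = round(cfg$viewing_duration_ms +
                                      sort(stats::runif(length(marks_x), 0, 10000)), 1))
  } else {
    empty_marks()
  }
  list(stream = stream, marks = marks,
       labels = labels %||% data.frame(participant_id = character(),
                                       polyp_id = character(),
                                       intended_outcome = character()))
}

#' Simulate a complete study and write it to disk
#'
#' Generates ground-truth ROIs, one gaze file per participant-image trial,
#' the pooled marks table, the trial manifest and the ground-truth label
#' table, all in the package's table formats. A fixed seed yields
#' byte-identical files.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_gaze Write one gaze TSV per trial (default). Disable to keep
#'   large studies in memory only; the manifest, ROI, marks and label tables
#'   are always written.
#' @return Invisibly, a `gazerr_study` list: `dir`, `manifest`, `rois`,
#'   `marks`, `labels`, and `streams` (the in-memory `gaze_stream`s, named
#'   `<participant>_<trial>`).
#' @export
simulate_study <- function(cfg, out_dir, write_gaze = TRUE) {
  dir.create(file.path(out_dir, "gaze"), recursive = TRUE, showWarnings = FALSE)
  rois <- with_substream(cfg$seed, 0, simulate_rois(cfg))
  n_img <- cfg$n_positive_images + cfg$n_negative_images
  image_ids <- sprintf("img%02d", seq_len(n_img))
  negative_images <- image_ids[seq_len(cfg$n_negative_images) + cfg$n_positive_images]

  trials <- list(); all_marks <- list(); all_labels <- list(); streams <- list()
  for (gi in seq_along(cfg$groups)) {
    group <- cfg$groups[[gi]]
    for (pi in seq_len(group$n_participants)) {
      participant_id <- sprintf("%s%02d", group$label, pi)
      for (ti in seq_len(n_img)) {
        image_id <- image_ids[ti]
        trial_id <- sprintf("t%02d", ti)
        rois_img <- rois[rois$image_id == image_id, , drop = FALSE]
        sim <- with_substream(cfg$seed, c(gi, pi, ti),
                              simulate_trial(cfg, group, rois_img,
                                             participant_id, trial_id,
                                             image_id))
        key <- paste0(participant_id, "_", trial_id)
        streams[[key]] <- sim$stream
        gf <- file.path("gaze", paste0(key, ".tsv"))
        if (write_gaze) write_gaze_stream(sim$stream, file.path(out_dir, gf))
        all_marks[[key]] <- sim$marks
        all_labels[[key]] <- sim$labels
        trials[[key]] <- data.frame(
          participant_id = participant_id, group = group$label,
          trial_id = trial_id, image_id = image_id,
          image_width = cfg$image_width, image_height = cfg$image_height,
          gaze_file = gf, scale = 1, offset_x = 0, offset_y = 0)
      }
    }
  }
  trials <- do.call(rbind, unname(trials))
  all_marks <- do.call(rbind, unname(all_marks))
  all_labels <- do.call(rbind, unname(all_labels))
  rownames(trials) <- rownames(all_marks) <- rownames(all_labels) <- NULL
  manifest <- list(trials = trials, negative_images = negative_images)
  write_roi_table(rois, file.path(out_dir, "rois.tsv"))
  write_marks(all_marks %||% empty_marks(), file.path(out_dir, "marks.tsv"))
  write_manifest(manifest, file.path(out_dir, "manifest.yaml"))
  write_tsv(all_labels, file.path(out_dir, "labels.tsv"))
  invisible(structure(list(dir = out_dir, manifest = manifest, rois = rois,
                           marks = all_marks %||% empty_marks(),
                           labels = all_labels, streams = streams),
                      class = "gazerr_study"))
}

#' @export
print.gazerr_study <- function(x, ...) {
  cat(sprintf("<gazerr_study> %d trials, %d polyps over %d images (+%d negative), %d labels\n  dir: %s\n",
              nrow(x$manifest$trials), nrow(x$rois),
              length(unique(x$rois$image_id)),
              length(x$manifest$negative_images), nrow(x$labels), x$dir))
  invisible(x)
}
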