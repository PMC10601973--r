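# End-to-end orchestration: raw binocular gaze -> merged positions ->
# fixations -> image frame -> encounter outcomes -> cohort summaries ->
# comparison report (+ heat maps and on-disk stage artifacts).

#' Run the full recognition-error pipeline
#'
#' For every trial in the manifest: merge the binocular stream, detect
#' fixations, map them to the image frame, and classify each of the image's
#' polyps as a correct detection, gaze error or cognitive error against the
#' participant's annotation marks. Cohorts are then summarized with exact
#' confidence intervals and compared pairwise.
#'
#' @param study A `gazerr_study` from [simulate_study()], or a path to a
#'   manifest YAML (gaze/ROI/mark files are resolved relative to its
#'   directory, `rois.tsv` and `marks.tsv` beside it).
#' @param params [fixation_params()].
#' @param out_dir Optional output directory; when given, writes
#'   `fixations.tsv`, `outcomes.tsv`, `false_positives.tsv`, `report.tsv`,
#'   `comparisons.tsv`, `report.txt`, per-image heat maps and `run_log.txt`.
#' @param test Group-comparison test, see [compose_report()].
#' @param roi_hit Fixation-in-region rule, see [evaluate_trial()].
#' @param level Confidence level for all intervals.
#' @param heatmaps Render per-image cumulative heat maps when writing output
#'   (default `TRUE`; cosmetic, kernel sigma = the dispersion threshold).
#' @return A `gazerr_result` list: `outcomes`, `false_positives`,
#'   `fixations` (image frame, with trial keys), `summaries` (per group),
#'   `report` (a [compose_report()] object), `params`.
#' @export
run_pipeline <- function(study, params = fixation_params(), out_dir = NULL,
                         test = c("fisher", "chi2", "chi2-yates"),
                         roi_hit = c("centroid", "any-sample"),
                         level = 0.95, heatmaps = TRUE) {
  test <- match.arg(test)
  roi_hit <- match.arg(roi_hit)
  if (is.character(study)) {
    base <- dirname(study)
    manifest <- read_manifest(study)
    rois <- read_roi_table(file.path(base, "rois.tsv"))
    marks <- read_marks(file.path(base, "marks.tsv"))
    streams <- NULL
  } else {
    base <- study$dir
    manifest <- study$manifest
    rois <- study$rois
    marks <- study$marks
    streams <- study$streams
  }
  trials <- manifest$trials
  negative <- manifest$negative_images
  pos_rois <- rois[!(rois$image_id %in% negative), , drop = FALSE]

  outcomes <- vector("list", nrow(trials))
  fps <- vector("list", nrow(trials))
  fixes <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    key <- paste0(tr$participant_id, "_", tr$trial_id)
    stream <- if (!is.null(streams)) {
      streams[[key]]
    } else {
      read_gaze_stream(file.path(base, tr$gaze_file))
    }
    if (is.null(stream)) stop_("pipeline stage 'input': no gaze stream for trial %s", key)
    fx <- detect_fixations(merge_binocular(stream), params)
    fx <- map_screen_to_image(fx, tr$scale, tr$offset_x, tr$offset_y,
                              tr$image_width, tr$image_height)
    rois_img <- rois[rois$image_id == tr$image_id &
                       !(tr$image_id %in% negative), , drop = FALSE]
    marks_img <- marks[marks$participant_id == tr$participant_id &
                         marks$image_id == tr$image_id, , drop = FALSE]
    ev <- evaluate_trial(fx, marks_img, rois_img, tr$participant_id,
                         tr$group, tr$image_id, roi_hit = roi_hit)
    outcomes[[i]] <- ev$outcomes
    fps[[i]] <- ev$false_positives
    if (nrow(fx) > 0) {
      fixes[[i]] <- cbind(participant_id = tr$participant_id,
                          trial_id = tr$trial_id, image_id = tr$image_id, fx)
    }
  }
  outcomes <- do.call(rbind, outcomes)
  false_positives <- do.call(rbind, fps)
  fixations <- do.call(rbind, fixes)
  rownames(outcomes) <- NULL

  groups <- unique(trials$group)
  n_polyps <- nrow(pos_rois)
  summaries <- lapply(groups, function(g) {
    grp_out <- outcomes[outcomes$group == g, , drop = FALSE]
    n_part <- length(unique(trials$participant_id[trials$group == g]))
    grp_fp <- false_positives[false_positives$participant_id %in%
                                trials$participant_id[trials$group == g], ,
                              drop = FALSE]
    summarize_group(grp_out, n_part, n_polyps,
                    false_positives = grp_fp, level = level)
  })
  names(summaries) <- groups
  report <- compose_report(summaries, test = test, level = level)

  result <- structure(list(outcomes = outcomes,
                           false_positives = false_positives,
                           fixations = fixations, summaries = summaries,
                           report = report, params = params),
                      class = "gazerr_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_outcomes(outcomes, file.path(out_dir, "outcomes.tsv"))
    write_tsv(false_positives, file.path(out_dir, "false_positives.tsv"))
    if (!is.null(fixations)) {
      write_tsv(fixations, file.path(out_dir, "fixations.tsv"))
    }
    write_report(report, file.path(out_dir, "report.tsv"),
                 file.path(out_dir, "report.txt"))
    write_tsv(report$comparisons, file.path(out_dir, "comparisons.tsv"))
    if (heatmaps && !is.null(fixations)) {
      for (img in unique(trials$image_id)) {
        fimg <- fixations[fixations$image_id == img, , drop = FALSE]
        dims <- trials[trials$image_id == img, ][1, ]
        hm <- render_heatmap(fimg, dims$image_width, dims$image_height,
                             kernel_sigma = params$dispersion_px)
        write_heatmap(hm, file.path(out_dir, sprintf("heatmap_%s.tsv", img)),
                      file.path(out_dir, sprintf("heatmap_%s.png", img)))
      }
    }
    log_lines <- c(
      sprintf("dispersion_px=%g", params$dispersion_px),
      sprintf("min_duration_ms=%g", params$min_duration_ms),
      sprintf("max_gap_ms=%g", params$max_gap_ms),
      sprintf("test=%s", test), sprintf("roi_hit=%s", roi_hit),
      sprintf("ci_level=%g", level),
      sprintf("n_trials=%d", nrow(trials)),
      sprintf("n_outcomes=%d", nrow(outcomes)),
      sprintf("n_false_positives=%d", nrow(false_positives)))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  result
}

#' @export
print.gazerr_result <- function(x, ...) {
  cat(sprintf("<gazerr_result> %d encounters, %d false-positive marks, %d fixations\n\n",
              nrow(x$outcomes), nrow(x$false_positives),
              if (is.null(x$fixations)) 0L else nrow(x$fixations)))
  print(x$report)
  invisible(x)
}

#' Agreement between pipeline outcomes and ground-truth labels
#'
#' @param outcomes Outcome rows (from a `gazerr_result`).
#' @param labels Ground-truth label rows from [simulate_study()]
#'   (`participant_id`, `polyp_id`, `intended_outcome`).
#' @return List with `agreement` (fraction of encounters classified
#'   identically) and `confusion` (intended x recovered table).
#' @export
label_agreement <- function(outcomes, labels) {
  m <- merge(outcomes[, c("participant_id", "polyp_id", "outcome")], labels,
             by = c("participant_id", "polyp_id"))
  if (nrow(m) != nrow(labels)) {
    stop_("outcomes and labels do not cover the same encounters")
  }
  list(agreement = mean(m$outcome == m$intended_outcome),
       confusion = table(intended = m$intended_outcome,
                         recovered = m$outcome))
}
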